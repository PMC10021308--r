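component,code,label
wall,11,no walls
wall,12,cane/palm/trunks
wall,13,dirt
wall,21,bamboo with mud
wall,22,stone with mud
wall,23,uncovered adobe
wall,24,plywood
wall,25,cardboard
wall,26,reused wood
wall,31,cement
wall,32,stone with lime/cement
wall,33,bricks
wall,34,cement blocks
wall,35,covered adobe
wall,36,wood planks/shingles
wall,96,other
roof,11,no roof
roof,12,thatch/palm leaf
roof,13,sod
roof,21,rustic mat
roof,22,palm/bamboo
roof,23,wood planks
roof,24,cardboard
roof,31,metal
roof,32,wood
roof,33,calamine/cement fiber
roof,34,ceramic tiles
roof,35,cement
roof,36,roofing shingles
roof,96,other
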