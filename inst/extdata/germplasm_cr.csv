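name,type,kasp_diplotype,array_diplotype,actual_ch
Panamint,Nectarine,H|H,,150
Tropic Prince,Peach,L|L,,150
TexFirst,Peach,L|L,,175
Diamante,Peach,L|LM,,294
A007,Peach,M|M,,350
A009,Peach,M|M,,350
A066,Peach,M|M,,350
A130,Peach,M|M,,350
A151,Peach,M|M,,350
A209,Peach,M|M,M|M,350
C005,Peach,L|L,,350
C008,Peach,L|L,,350
C045,Peach,L|L,,350
Desert Gold,Peach,L|L,,350
Peento,Peach,M|M,L|M,450
Sunlite,Nectarine,H|M,,450
Galaxy,Peach,M|M,M|M,550
Bradley,Nectarine,M|M,M|M,650
Empress,Peach,M|LM,,650
Fairlane,Nectarine,M|M,,650
LeGrand,Nectarine,M|M,,650
Springprince,Peach,M|LM,M|LM,650
Springtime,Peach,H|LM,H|LM,650
Suncrest,Peach,H|M,,650
Kakamas,Peach,LM|LM,,675
Coronet,Peach,M|LM,,700
Crimson Lady,Peach,M|LM,M|LM,700
Fortyniner,Peach,H|H,,700
Saturn,Peach,M|M,L|M,700
Stark Saturn,Peach,H|M,,700
Caroking,Peach,M|M,M|M,750
Chinese Cling,Peach,M|M,M|M,750
Dwarf Elberta,Peach,H|M,,750
Fantasia,Nectarine,M|M,H|M,750
Federica,Peach,M|M,,750
Flavorcrest,Peach,M|M,,750
Flavortop,Nectarine,H|M,,750
Harvester,Peach,M|M,M|M,750
Hiley,Peach,H|H,H|H,750
Slappey,Peach,H|M,H|M,750
White Hale,Peach,M|M,,750
Westbrook,Nectarine,M|M,M|M,750
Joanna Sweet,Peach,M|M,,800
Loring,Peach,M|M,M|M,800
O'Henry,Peach,H|M,H|M,800
Orange Cling,Peach,H|H,H|H,800
Cumberland,Peach,M|M,M|M,850
Fayette,Peach,M|M,M|M,850
Harblaze,Nectarine,H|M,,850
JH Hale,Peach,M|M,M|M,850
Julyprince,Peach,H|M,H|M,850
Red Baron,Peach,H|M,,850
Redglobe,Peach,H|M,H|M,850
Redtop,Peach,H|M,,850
Rio Oso Gem,Peach,H|M,H|M,850
Somervee,Peach,H|M,,850
Summerprince,Peach,M|M,M|M,850
Vinegold,Peach,M|M,,850
Hakuho,Peach,H|M,H|M,900
September Snow,Peach,H|LM,,900
Biscoe,Peach,M|M,M|M,925
Candor,Peach,H|H,H|H,950
Cardinal,Peach,M|M,,950
Champion,Peach,H|H,,950
Cresthaven,Peach,H|M,,950
Dixired,Peach,H|M,,950
Early Crawford,Peach,H|H,H|H,950
Harrow Diamond,Peach,H|M,,950
Marigold,Peach,M|M,,950
Morton,Nectarine,H|H,,950
Redhaven,Peach,H|M,H|M,950
Vivid,Peach,M|M,,950
White Heath Cling,Peach,H|H,,950
Admiral Dewey,Peach,H|H,H|H,1000
Greensboro,Peach,M|M,M|M,1000
Intrepid,Peach,H|M,H|M,1050
Nectar,Peach,H|H,,1050
Salway,Peach,H|H,,1050
China Pearl,Peach,H|M,H|M,1100
Polly,Peach,H|M,,1100
Mountain Rose,Peach,H|M,,1150
Yumyeong,Peach,M|M,M|M,1200
Amarillo Tardio,Peach,H|H,,1300
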