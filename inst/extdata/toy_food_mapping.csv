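food_code,group_id,split
11000001,,dairy_fat
11000002,,dairy_fat
23000001,G3,none
24000001,G4,none
26000001,G6,none
31000001,G9,none
41000001,G10,none
42000001,G11,none
51000001,G12,none
53000001,G13,none
54000001,G14,none
56000001,G16,none
57000001,,grain_fiber
57000002,,grain_fiber
61000001,G22,none
64000001,G23,none
71000001,G24,none
72000001,G25,none
74000001,G26,none
75000001,G27,none
81000001,G28,none
82000001,G29,none
83000001,G30,none
91000001,G31,none
92000001,G32,none
93000001,G33,none
95000001,G34,none
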