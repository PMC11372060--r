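genome,anchor,kaiA3,kaiB3,kaiC3,bg01,bg02,bg03,bg04
genome001,1,1,1,1,1,1,1,1
genome002,1,1,1,1,1,1,1,1
genome003,1,1,1,1,0,0,0,1
genome004,1,0,0,0,1,1,1,1
genome005,1,1,1,1,0,1,1,0
genome006,0,0,0,0,1,1,0,0
genome007,1,0,0,0,1,1,1,1
genome008,1,1,1,1,0,0,1,1
genome009,0,0,0,0,0,0,0,1
genome010,1,0,0,0,1,0,1,0
genome011,1,0,0,0,1,0,1,0
genome012,1,0,0,0,0,0,0,0
genome013,0,0,0,0,1,1,1,0
genome014,0,0,0,0,1,0,0,0
genome015,1,1,1,1,0,1,0,1
genome016,1,1,1,1,1,1,0,0
genome017,1,1,1,1,0,1,1,0
genome018,1,0,0,0,1,0,0,0
genome019,1,1,1,1,0,0,1,0
genome020,1,0,0,0,1,0,1,0
genome021,1,1,1,1,0,0,0,0
genome022,1,0,0,0,0,0,1,0
genome023,1,1,1,1,1,1,1,0
genome024,1,0,0,0,1,0,1,0
genome025,1,0,0,0,1,1,0,0
genome026,1,1,1,1,1,0,1,0
genome027,1,1,1,1,0,0,1,1
genome028,1,1,1,1,0,1,1,1
genome029,1,1,1,1,0,0,0,1
genome030,1,0,0,0,1,1,0,1
genome031,1,0,0,0,0,0,1,1
genome032,1,0,1,1,1,0,1,1
genome033,1,1,1,1,1,1,0,1
genome034,1,1,1,1,0,0,0,0
genome035,1,0,0,0,0,0,1,0
genome036,1,0,0,0,1,0,0,0
genome037,1,1,1,1,0,1,0,1
genome038,1,1,1,1,1,1,0,0
genome039,1,1,1,1,0,0,1,0
genome040,1,1,1,1,1,0,0,1
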