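participant_id,mal01,mal02,mal03,mal04,mal05,mal06,mal07,mal08,mal09,mal10,mal11,mal12,mal13,mal14,mal15,mal16,mal17,mal18,mal19,mal20,mal21,mal22,mal23,mal24,mal25,mal26,mal27
C01,2,1,0,2,1,0,2,1,0,2,1,0,2,1,0,2,1,0,2,1,0,2,1,0,2,1,0
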