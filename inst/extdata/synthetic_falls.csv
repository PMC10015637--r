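subject_id,past_6mo_falls,period_start,period_end,n_falls,n_near_falls
S01,0,0,182,1,1
S01,0,182,364,2,0
S02,0,0,182,1,2
S02,0,182,364,1,0
S03,0,0,182,1,0
S03,0,182,364,2,0
S04,0,0,182,1,1
S04,0,182,364,1,0
S05,0,0,182,1,2
S05,0,182,364,2,0
S06,0,0,182,1,0
S06,0,182,364,1,0
S07,0,0,182,1,1
S07,0,182,364,2,0
S08,0,0,182,1,2
S08,0,182,364,1,0
S09,0,0,182,1,0
S09,0,182,364,2,0
S10,0,0,182,1,1
S10,0,182,364,1,0
S11,0,0,182,1,2
S11,0,182,364,2,0
S12,0,0,182,1,0
S12,0,182,364,1,0
S13,0,0,182,1,1
S13,0,182,364,2,0
S14,0,0,182,1,2
S14,0,182,364,1,0
S15,0,0,182,1,0
S15,0,182,364,2,0
S16,0,0,182,1,1
S16,0,182,364,1,0
S17,0,0,182,1,2
S17,0,182,364,2,0
S18,1,0,182,1,0
S18,1,182,364,1,0
S19,1,0,182,1,1
S19,1,182,364,2,0
S20,1,0,182,1,2
S20,1,182,364,1,0
S21,1,0,182,1,0
S21,1,182,364,0,0
S22,1,0,182,0,1
S22,1,182,364,1,0
S23,1,0,182,1,2
S23,1,182,364,0,0
S24,1,0,182,0,0
S24,1,182,364,1,0
S25,1,0,182,1,1
S25,1,182,364,0,0
S26,1,0,182,0,2
S26,1,182,364,0,0
S27,1,0,182,0,0
S27,1,182,364,0,0
S28,1,0,182,0,1
S28,1,182,364,0,0
S29,1,0,182,0,2
S29,1,182,364,0,0
S30,1,0,182,0,0
S30,1,182,364,0,0
S31,1,0,182,0,1
S31,1,182,364,0,0
S32,1,0,182,0,2
S32,1,182,364,0,0
S33,1,0,182,0,0
S33,1,182,364,0,0
S34,1,0,182,0,1
S34,1,182,364,0,0
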