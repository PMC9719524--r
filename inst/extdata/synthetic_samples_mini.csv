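sample_id,sex,site,cluster
C1_M01,M,site_1,1
C1_M02,M,site_1,1
C1_M03,M,site_1,1
C1_M04,M,site_1,1
C1_F01,F,site_1,1
C1_F02,F,site_1,1
C1_F03,F,site_1,1
C1_F04,F,site_1,1
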