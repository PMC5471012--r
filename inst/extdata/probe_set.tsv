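probe_id	gene	role	fusion_id	nominal_amount
ALK_5p_e02	ALK	five_prime	.	.
ALK_5p_e09	ALK	five_prime	.	.
ALK_5p_e18	ALK	five_prime	.	.
ALK_3p_e21	ALK	three_prime	.	.
ALK_3p_e24	ALK	three_prime	.	.
ALK_3p_e28	ALK	three_prime	.	.
RET_5p_e04	RET	five_prime	.	.
RET_5p_e08	RET	five_prime	.	.
RET_5p_e10	RET	five_prime	.	.
RET_3p_e13	RET	three_prime	.	.
RET_3p_e16	RET	three_prime	.	.
RET_3p_e19	RET	three_prime	.	.
ROS1_5p_e10	ROS1	five_prime	.	.
ROS1_5p_e20	ROS1	five_prime	.	.
ROS1_5p_e30	ROS1	five_prime	.	.
ROS1_3p_e37	ROS1	three_prime	.	.
ROS1_3p_e40	ROS1	three_prime	.	.
ROS1_3p_e43	ROS1	three_prime	.	.
FS_EML4-ALK_E13:A20	ALK	fusion_specific	EML4-ALK_E13:A20	.
FS_EML4-ALK_E6ab:A20	ALK	fusion_specific	EML4-ALK_E6ab:A20	.
FS_EML4-ALK_E20:A20	ALK	fusion_specific	EML4-ALK_E20:A20	.
FS_NPM1-ALK_N4:A20	ALK	fusion_specific	NPM1-ALK_N4:A20	.
FS_KIF5B-ALK_K24:A20	ALK	fusion_specific	KIF5B-ALK_K24:A20	.
FS_CCDC6-RET_C1:R12	RET	fusion_specific	CCDC6-RET_C1:R12	.
FS_KIF5B-RET_K15:R12	RET	fusion_specific	KIF5B-RET_K15:R12	.
FS_NCOA4-RET_N7:R12	RET	fusion_specific	NCOA4-RET_N7:R12	.
FS_SLC34A2-ROS1_S4:R32	ROS1	fusion_specific	SLC34A2-ROS1_S4:R32	.
FS_SDC4-ROS1_S2:R32	ROS1	fusion_specific	SDC4-ROS1_S2:R32	.
FS_CD74-ROS1_C6:R34	ROS1	fusion_specific	CD74-ROS1_C6:R34	.
FS_EZR-ROS1_E10:R34	ROS1	fusion_specific	EZR-ROS1_E10:R34	.
HK_ACTB	.	housekeeping	.	.
HK_GAPDH	.	housekeeping	.	.
HK_GUSB	.	housekeeping	.	.
HK_OAZ1	.	housekeeping	.	.
HK_POLR2A	.	housekeeping	.	.
HK_RPLP0	.	housekeeping	.	.
HK_TBP	.	housekeeping	.	.
POS_A	.	pos_control	.	128
POS_B	.	pos_control	.	32
POS_C	.	pos_control	.	8
POS_D	.	pos_control	.	2
POS_E	.	pos_control	.	0.5
POS_F	.	pos_control	.	0.125
NEG_A	.	neg_control	.	.
NEG_B	.	neg_control	.	.
NEG_C	.	neg_control	.	.
NEG_D	.	neg_control	.	.
NEG_E	.	neg_control	.	.
NEG_F	.	neg_control	.	.
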