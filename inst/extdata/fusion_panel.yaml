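- gene: ALK
  probe_id: ALK_5p_1
  role: five_prime
  group: ''
- gene: ALK
  probe_id: ALK_5p_2
  role: five_prime
  group: ''
- gene: ALK
  probe_id: ALK_5p_3
  role: five_prime
  group: ''
- gene: ALK
  probe_id: ALK_3p_1
  role: three_prime
  group: ''
- gene: ALK
  probe_id: ALK_3p_2
  role: three_prime
  group: ''
- gene: ALK
  probe_id: ALK_3p_3
  role: three_prime
  group: ''
- gene: ALK
  probe_id: ALK_jx_E6B_A20
  role: junction
  group: EML4-ALK_E6B:A20
- gene: ALK
  probe_id: ALK_jx_E13_A20
  role: junction
  group: EML4-ALK_E13:A20
- gene: ALK
  probe_id: ALK_jx_E20_A20
  role: junction
  group: EML4-ALK_E20:A20
- gene: RET
  probe_id: RET_5p_1
  role: five_prime
  group: ''
- gene: RET
  probe_id: RET_5p_2
  role: five_prime
  group: ''
- gene: RET
  probe_id: RET_5p_3
  role: five_prime
  group: ''
- gene: RET
  probe_id: RET_3p_1
  role: three_prime
  group: ''
- gene: RET
  probe_id: RET_3p_2
  role: three_prime
  group: ''
- gene: RET
  probe_id: RET_3p_3
  role: three_prime
  group: ''
- gene: RET
  probe_id: RET_jx_K15_R12
  role: junction
  group: KIF5B-RET_K15:R12
- gene: RET
  probe_id: RET_jx_K16_R12
  role: junction
  group: KIF5B-RET_K16:R12
- gene: RET
  probe_id: RET_jx_C1_R12
  role: junction
  group: CCDC6-RET_C1:R12
- gene: ROS1
  probe_id: ROS1_5p_1
  role: five_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_5p_2
  role: five_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_5p_3
  role: five_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_3p_1
  role: three_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_3p_2
  role: three_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_3p_3
  role: three_prime
  group: ''
- gene: ROS1
  probe_id: ROS1_jx_C6_R34
  role: junction
  group: CD74-ROS1_C6:R34
- gene: ROS1
  probe_id: ROS1_jx_S4_R32
  role: junction
  group: SLC34A2-ROS1_S4:R32
- gene: NRG1
  probe_id: NRG1_5p_1
  role: five_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_5p_2
  role: five_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_5p_3
  role: five_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_3p_1
  role: three_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_3p_2
  role: three_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_3p_3
  role: three_prime
  group: ''
- gene: NRG1
  probe_id: NRG1_jx_C8_N6
  role: junction
  group: CD74-NRG1_C8:N6
- gene: NTRK1
  probe_id: NTRK1_5p_1
  role: five_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_5p_2
  role: five_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_5p_3
  role: five_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_3p_1
  role: three_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_3p_2
  role: three_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_3p_3
  role: three_prime
  group: ''
- gene: NTRK1
  probe_id: NTRK1_jx_T7_N10
  role: junction
  group: TPM3-NTRK1_T7:N10
- gene: MET
  probe_id: MET_ex3
  role: exon_group
  group: exons_3_4
- gene: MET
  probe_id: MET_ex4
  role: exon_group
  group: exons_3_4
- gene: MET
  probe_id: MET_ex14
  role: exon_group
  group: exon_14
- gene: MET
  probe_id: MET_ex20
  role: exon_group
  group: exons_20_21
- gene: MET
  probe_id: MET_ex21
  role: exon_group
  group: exons_20_21
- gene: MET
  probe_id: MET_jx_ex13_15
  role: junction
  group: exon14_skipping
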