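group_name,member_gene
TRAV1-1,TRAV1-1
TRAV1-2,TRAV1-2
TRAV2,TRAV2
TRAV3,TRAV3
TRAV4,TRAV4
TRAV5,TRAV5
TRAV6,TRAV6
TRAV7,TRAV7
TRAV8-1,TRAV8-1
TRAV8-2/8-4,TRAV8-2
TRAV8-3,TRAV8-3
TRAV8-2/8-4,TRAV8-4
TRAV9-1,TRAV9-1
TRAV9-2,TRAV9-2
TRAV10,TRAV10
TRAV12-1,TRAV12-1
TRAV12-2,TRAV12-2
TRAV13-1,TRAV13-1
TRAV13-2,TRAV13-2
TRAV14/DV4,TRAV14/DV4
TRAV16,TRAV16
TRAV17,TRAV17
TRAV18,TRAV18
TRAV19,TRAV19
TRAV20,TRAV20
TRAV21,TRAV21
TRAV23/DV6,TRAV23/DV6
TRAV24,TRAV24
TRAV25,TRAV25
TRAV26-1,TRAV26-1
TRAV26-2,TRAV26-2
TRAV27,TRAV27
TRAV29/DV5,TRAV29/DV5
TRAV34,TRAV34
TRAV35,TRAV35
TRAV36/DV7,TRAV36/DV7
TRAV38-1,TRAV38-1
TRAV38-2/DV8,TRAV38-2/DV8
TRAV39,TRAV39
TRAV40,TRAV40
TRAV41,TRAV41
TRAJ9,TRAJ9
TRAJ12,TRAJ12
TRAJ20,TRAJ20
TRAJ23,TRAJ23
TRAJ30,TRAJ30
TRAJ33,TRAJ33
TRAJ42,TRAJ42
TRAJ49,TRAJ49
TRBV2,TRBV2
TRBV3-1,TRBV3-1
TRBV4-1,TRBV4-1
TRBV4-2,TRBV4-2
TRBV5-1,TRBV5-1
TRBV5-4,TRBV5-4
TRBV6-1,TRBV6-1
TRBV6-2/6-3,TRBV6-2
TRBV6-2/6-3,TRBV6-3
TRBV6-5,TRBV6-5
TRBV6-6,TRBV6-6
TRBV7-2,TRBV7-2
TRBV7-3,TRBV7-3
TRBV7-9,TRBV7-9
TRBV9,TRBV9
TRBV10-3,TRBV10-3
TRBV11-1,TRBV11-1
TRBV11-2,TRBV11-2
TRBV11-3,TRBV11-3
TRBV12-3/12-4,TRBV12-3
TRBV12-3/12-4,TRBV12-4
TRBV13,TRBV13
TRBV14,TRBV14
TRBV15,TRBV15
TRBV16,TRBV16
TRBV18,TRBV18
TRBV19,TRBV19
TRBV20-1,TRBV20-1
TRBV24-1,TRBV24-1
TRBV25-1,TRBV25-1
TRBV27,TRBV27
TRBV28,TRBV28
TRBV29-1,TRBV29-1
TRBV30,TRBV30
TRBJ1-1,TRBJ1-1
TRBJ2-1,TRBJ2-1
TRGV2,TRGV2
TRGV3/5,TRGV3
TRGV4,TRGV4
TRGV3/5,TRGV5
TRGV8,TRGV8
TRGV9,TRGV9
TRDV1,TRDV1
TRDV2,TRDV2
TRDV3,TRDV3
TRAC,TRAC
TRBC1/2,TRBC1
TRBC1/2,TRBC2
TRDC,TRDC
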