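site,field_id,name,adults,tadpoles,screened_tadpoles,final_n
1,3008,Laramie Lake North,9,0,0,9
2,3107,Spruce bog,3,30,24,27
3,3109,Laramie Lake South,11,0,0,11
4,3111,Spencer 7,2,0,0,2
5,3111.2,Old Highway 14,8,19,14,22
6,3112,Sylvatica,29,40,31,60
7,3113,Spencer 16,5,0,0,5
8,3114,Spencer 12,2,30,14,16
9,3114.3,Spencer 11,0,30,27,27
10,3117,Lily,19,0,0,19
11,3117.2,Mosquitos,11,0,0,11
12,3118,Matthews,13,0,0,13
13,3119,Zimmerman 1,0,31,28,28
14,3121.1,Zimmerman 6,0,27,27,27
15,3121.2,Zimmerman 5,0,5,5,5
16,3122.1,Tunnel B,0,30,14,14
17,3124,Lily Pond Lake,2,32,22,24
18,3126,Mosquito 2,2,0,0,2
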