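reaction_index,parameter,value
1,Vmax1,14
1,Km1,2
1,Ki1,600
2,k2,12
3,k3,25
4,Vmax4,4
4,Km4,2
5,Vmax5,45
5,Km5,1
6,Vmax6,3
6,Km6,2
7,Vmax7,8
7,Km7,30
8,Vmax8,8
8,Km8a,30
8,Km8b,0.5
8,Ki8,4
9,Vmax9,12
9,Km9,1
10,Vmax10,60
10,Km10,5
10,Ki10,80
11,Vmax11,2.5
11,Km11,1
11,Ka11,5
12,Vmax12,2
12,Km12,1
13,Vmax13,1.2
13,Km13,8
14,Vmax14,28
14,Km14,0.5
14,Ki14,90
15,Vmax15,6
15,Km15a,15
15,Km15b,0.5
15,Ki15,4
16,Vmax16,20
16,Km16,1
17,Vmax17,8
17,Km17,20
17,Ki17,250
18,Vmax18,22
18,Km18,1
19,Vmax19,26
19,Km19,1
19,Ka19,10
20,Vmax20,16
20,Km20,2.5
21,Vmax21,6.5
21,Km21,2
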