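"run_id","point_type","coded_SW","coded_AM","coded_EV","coded_WC","coded_ET","SW","AM","EV","WC","ET"
1,"factorial",-1,-1,-1,-1,-1,2.4,5,8,1.5,1
2,"factorial",-1,-1,-1,-1,1,2.4,5,8,1.5,3
3,"factorial",-1,-1,-1,1,-1,2.4,5,8,4.5,1
4,"factorial",-1,-1,-1,1,1,2.4,5,8,4.5,3
5,"factorial",-1,-1,1,-1,-1,2.4,5,16,1.5,1
6,"factorial",-1,-1,1,-1,1,2.4,5,16,1.5,3
7,"factorial",-1,-1,1,1,-1,2.4,5,16,4.5,1
8,"factorial",-1,-1,1,1,1,2.4,5,16,4.5,3
9,"factorial",-1,1,-1,-1,-1,2.4,95,8,1.5,1
10,"factorial",-1,1,-1,-1,1,2.4,95,8,1.5,3
11,"factorial",-1,1,-1,1,-1,2.4,95,8,4.5,1
12,"factorial",-1,1,-1,1,1,2.4,95,8,4.5,3
13,"factorial",-1,1,1,-1,-1,2.4,95,16,1.5,1
14,"factorial",-1,1,1,-1,1,2.4,95,16,1.5,3
15,"factorial",-1,1,1,1,-1,2.4,95,16,4.5,1
16,"factorial",-1,1,1,1,1,2.4,95,16,4.5,3
17,"factorial",1,-1,-1,-1,-1,5.8,5,8,1.5,1
18,"factorial",1,-1,-1,-1,1,5.8,5,8,1.5,3
19,"factorial",1,-1,-1,1,-1,5.8,5,8,4.5,1
20,"factorial",1,-1,-1,1,1,5.8,5,8,4.5,3
21,"factorial",1,-1,1,-1,-1,5.8,5,16,1.5,1
22,"factorial",1,-1,1,-1,1,5.8,5,16,1.5,3
23,"factorial",1,-1,1,1,-1,5.8,5,16,4.5,1
24,"factorial",1,-1,1,1,1,5.8,5,16,4.5,3
25,"factorial",1,1,-1,-1,-1,5.8,95,8,1.5,1
26,"factorial",1,1,-1,-1,1,5.8,95,8,1.5,3
27,"factorial",1,1,-1,1,-1,5.8,95,8,4.5,1
28,"factorial",1,1,-1,1,1,5.8,95,8,4.5,3
29,"factorial",1,1,1,-1,-1,5.8,95,16,1.5,1
30,"factorial",1,1,1,-1,1,5.8,95,16,1.5,3
31,"factorial",1,1,1,1,-1,5.8,95,16,4.5,1
32,"factorial",1,1,1,1,1,5.8,95,16,4.5,3
33,"axial",-1,0,0,0,0,2.4,50,12,3,2
34,"axial",1,0,0,0,0,5.8,50,12,3,2
35,"axial",0,-1,0,0,0,4.1,5,12,3,2
36,"axial",0,1,0,0,0,4.1,95,12,3,2
37,"axial",0,0,-1,0,0,4.1,50,8,3,2
38,"axial",0,0,1,0,0,4.1,50,16,3,2
39,"axial",0,0,0,-1,0,4.1,50,12,1.5,2
40,"axial",0,0,0,1,0,4.1,50,12,4.5,2
41,"axial",0,0,0,0,-1,4.1,50,12,3,1
42,"axial",0,0,0,0,1,4.1,50,12,3,3
43,"center",0,0,0,0,0,4.1,50,12,3,2
44,"center",0,0,0,0,0,4.1,50,12,3,2
45,"center",0,0,0,0,0,4.1,50,12,3,2
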