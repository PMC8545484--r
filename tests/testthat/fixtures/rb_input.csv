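20,19,22,22,20,21,23,23,24,24,26,26,26,28,27,27,28,28,30,29,30,30,32,31,32,32,34,34,34,35,37,35,35,36,38,39,38,38,38,40,41,41,40,42,42,43,44,44
21,21,22,22,21,22,23,23,24,26,24,27,25,26,27,28,29,30,29,29,31,31,30,31,31,33,33,34,34,35,36,35,37,36,37,37,37,39,39,40,41,41,42,42,42,43,42,42
19,20,22,21,22,24,23,25,24,25,25,26,27,25,28,28,28,28,30,30,31,31,33,32,32,33,34,35,35,35,37,35,36,36,37,37,39,39,38,39,41,42,44,45,43,42,41,44
20,21,21,22,24,24,24,23,23,25,26,28,27,28,27,27,28,29,32,30,32,30,33,33,33,33,33,35,34,34,35,37,38,38,38,39,40,40,39,42,41,43,42,41,42,45,46,44
21,23,21,22,24,23,24,25,26,27,26,27,25,28,27,27,28,29,31,29,31,31,32,34,34,35,34,34,35,36,36,36,37,38,41,41,38,39,39,40,42,43,41,42,41,44,43,44
21,22,21,22,26,23,23,27,28,25,26,27,29,27,28,30,30,30,30,30,31,32,33,32,34,35,35,35,36,36,36,37,37,40,40,39,39,39,42,41,42,40,43,43,42,44,45,45
22,22,23,23,25,22,25,25,26,26,25,28,30,27,30,30,30,30,31,33,32,34,34,34,36,35,36,35,36,36,38,36,39,38,40,40,42,41,39,41,41,42,44,44,43,43,45,44
21,23,24,24,22,25,25,26,28,25,27,28,27,32,32,34,32,33,33,32,32,33,32,33,34,35,36,35,36,38,36,37,38,39,39,41,41,41,42,44,42,41,45,43,44,46,43,44
21,22,24,24,25,23,23,26,26,27,28,29,32,36,41,42,41,38,35,33,33,33,33,35,32,34,34,34,36,38,37,38,39,40,39,41,40,40,41,40,42,43,44,46,43,45,44,46
23,21,25,24,24,24,25,27,27,28,29,33,38,48,63,67,64,52,41,36,35,35,34,34,36,34,36,36,37,36,36,36,38,39,39,42,42,40,42,42,42,43,44,44,46,44,46,49
23,25,24,25,25,25,25,27,26,28,31,36,49,74,99,112,99,75,50,38,36,35,33,33,32,35,38,37,36,38,36,38,39,39,41,41,42,41,43,44,42,43,45,44,46,45,47,47
24,25,24,24,25,26,25,27,27,29,29,39,60,98,141,159,141,101,65,43,37,35,35,35,36,38,36,36,37,37,37,38,39,40,40,40,42,43,42,42,44,44,43,45,46,45,46,45
25,25,24,25,23,25,26,26,28,31,31,41,67,113,158,181,162,111,69,45,36,35,35,33,36,36,38,36,37,39,39,40,38,41,40,41,40,43,42,42,44,44,44,47,45,46,47,46
24,24,24,27,25,24,29,30,28,27,31,40,62,99,142,160,141,102,67,44,36,35,36,34,36,36,39,37,40,37,39,40,39,41,42,41,40,42,42,43,44,43,43,46,45,44,48,48
23,23,26,26,29,27,28,28,29,30,32,36,50,74,101,114,101,76,54,40,37,33,34,35,34,36,36,37,39,38,38,40,41,40,40,42,42,43,43,44,43,45,45,44,45,47,47,47
24,26,23,25,26,28,28,29,27,28,31,33,40,51,64,70,65,54,41,35,36,36,34,34,37,38,39,39,38,38,40,40,39,43,43,43,42,44,44,44,46,46,46,47,47,45,48,47
24,27,28,28,27,29,28,29,28,30,30,30,34,38,44,46,44,40,37,35,34,35,35,35,37,38,36,38,40,40,41,40,40,40,42,43,44,44,44,43,44,46,46,46,47,47,47,49
25,26,26,25,27,29,27,26,27,30,30,31,33,31,35,37,35,35,34,34,35,37,38,36,39,38,40,39,39,40,43,41,40,43,42,42,44,44,44,45,45,46,44,47,46,46,48,49
25,27,25,26,27,28,29,28,30,30,29,29,32,32,33,33,34,35,33,34,34,36,38,36,35,36,38,38,39,40,40,42,41,41,43,41,44,44,44,46,45,48,46,46,47,47,48,49
26,26,28,28,29,29,30,27,29,29,31,31,32,34,33,34,34,34,35,36,37,38,37,38,37,38,40,40,40,41,41,42,42,42,43,40,44,41,43,46,46,45,46,49,47,50,49,50
28,27,26,27,28,27,29,29,31,31,31,31,32,33,32,32,35,34,34,36,36,35,37,38,38,39,38,40,40,40,42,43,44,44,43,44,45,45,45,46,46,46,47,48,48,49,50,49
27,27,26,29,28,27,28,29,30,31,31,32,33,33,34,34,32,34,33,36,36,38,38,38,38,39,39,40,41,40,42,42,41,44,44,44,44,44,45,46,45,47,46,48,48,51,48,51
27,28,28,29,28,31,29,31,30,31,31,33,34,33,33,33,34,34,35,36,38,40,37,40,39,39,40,40,41,41,40,41,43,43,43,44,45,45,45,47,48,48,49,49,50,50,50,51
26,28,27,28,30,30,31,30,30,31,32,32,34,33,34,33,35,35,35,36,37,37,40,38,39,37,39,40,40,43,42,44,43,43,44,44,47,43,44,46,47,48,48,48,50,50,50,51
27,27,29,29,29,31,28,29,30,31,32,31,32,33,37,37,35,35,35,35,37,37,38,37,38,40,41,41,40,43,41,43,43,43,44,45,46,46,48,48,47,48,50,51,48,49,52,50
26,28,29,29,29,29,30,30,34,32,33,33,33,33,32,34,34,34,35,38,37,39,39,40,39,41,41,40,42,43,42,42,43,46,47,46,47,47,47,49,49,47,50,48,51,50,50,49
28,27,30,31,29,31,30,31,33,32,35,33,35,34,36,35,36,36,36,38,38,39,40,41,39,41,40,41,41,44,44,45,49,49,50,53,50,48,46,47,50,49,49,49,49,48,51,52
27,28,28,29,30,29,32,32,32,30,32,35,31,34,34,36,35,37,38,39,38,39,38,41,39,40,41,40,42,44,45,48,56,65,66,64,59,52,49,50,49,49,52,49,49,51,52,51
27,31,30,29,31,31,31,32,31,33,35,34,34,34,35,36,36,38,36,39,38,39,38,41,42,42,40,43,43,42,47,56,71,87,94,89,74,56,51,49,47,49,51,49,51,50,51,53
28,30,28,32,31,31,32,31,34,33,33,34,34,36,36,37,37,38,37,40,37,40,41,39,43,42,43,42,43,45,51,65,86,110,124,113,89,67,54,49,48,48,50,50,50,48,50,53
28,30,29,32,31,32,34,34,33,33,34,35,35,35,37,36,39,38,40,39,40,39,39,41,42,42,41,41,42,44,52,68,94,120,136,123,98,68,55,52,50,50,50,51,52,51,53,51
30,30,30,31,31,31,32,32,34,33,35,34,35,35,38,37,37,38,36,39,41,40,40,41,42,40,41,43,43,47,51,62,86,109,123,113,88,68,56,50,47,50,51,51,52,51,54,52
30,28,30,33,31,33,33,33,35,34,33,34,36,36,35,36,37,38,37,38,39,41,41,41,41,42,42,42,43,44,48,57,73,86,95,88,74,60,51,49,50,51,48,51,53,52,53,52
30,29,29,32,31,32,32,32,34,34,35,36,36,37,38,36,38,40,40,38,40,42,41,42,42,42,43,43,44,45,46,52,61,64,70,66,61,54,52,51,50,52,49,53,52,53,52,53
30,31,31,33,30,34,33,34,33,36,33,37,35,37,37,39,38,38,39,41,41,40,41,40,43,41,44,44,47,44,46,49,52,53,55,54,53,50,50,48,50,51,51,50,53,53,52,53
29,30,31,33,32,34,33,35,36,38,37,37,36,37,36,38,38,41,38,40,39,41,42,40,43,45,43,44,46,45,45,44,48,49,48,50,49,49,50,49,52,50,51,54,54,53,53,53
31,31,32,32,33,32,34,38,39,44,45,45,42,41,39,37,40,39,39,41,40,42,41,42,42,43,45,45,47,48,45,46,46,47,48,48,48,49,49,51,50,54,51,52,52,55,55,55
30,32,31,34,34,34,34,41,52,62,67,61,54,46,39,39,39,39,38,40,41,41,42,42,43,44,44,44,45,44,47,47,47,49,46,47,49,50,50,50,52,53,53,52,51,54,55,55
31,33,33,34,33,35,41,51,69,92,102,92,73,54,45,39,39,40,41,39,40,40,42,42,43,45,44,45,45,47,47,46,47,49,49,48,50,49,52,52,52,52,52,54,53,54,55,54
31,31,32,31,35,38,45,59,92,126,139,125,91,64,46,42,39,41,42,40,41,40,42,43,42,45,44,44,45,47,47,47,48,47,49,49,49,51,50,52,52,49,54,50,53,55,54,54
31,34,31,35,34,36,45,64,102,140,155,140,102,70,48,44,40,39,40,41,41,43,42,41,44,43,44,45,45,49,47,48,46,48,49,48,51,49,51,51,52,52,53,53,53,55,55,55
32,34,33,34,35,39,43,62,90,125,142,126,94,64,48,42,40,41,42,41,41,41,44,44,45,46,45,46,47,47,47,50,48,48,50,50,49,52,51,51,53,53,52,56,55,55,57,56
33,32,34,35,35,36,41,52,70,91,103,91,74,55,46,41,42,41,42,43,42,44,43,44,46,46,48,45,45,46,48,49,49,48,50,49,52,54,52,53,52,51,53,53,53,57,56,56
33,33,35,34,36,36,38,42,51,63,68,63,55,47,40,40,41,42,41,43,44,44,44,44,44,46,46,47,47,48,48,49,50,49,48,52,51,50,51,53,53,53,55,53,54,56,56,57
34,34,35,34,35,36,37,40,43,46,48,47,45,42,43,40,42,43,42,45,43,44,43,44,45,47,47,48,47,47,51,49,48,49,49,52,51,52,52,53,52,53,54,55,56,55,57,56
33,33,36,36,36,37,40,36,38,40,40,40,41,39,41,41,42,43,43,43,46,44,43,44,44,46,46,47,50,49,49,48,49,50,51,49,51,52,52,52,53,54,55,56,57,56,56,57
34,34,36,36,37,38,36,37,38,39,39,38,40,40,41,41,41,43,43,44,46,45,45,44,45,48,46,46,48,48,48,49,51,49,49,52,52,52,51,53,54,55,54,55,56,54,58,56
34,35,36,36,34,36,37,37,39,39,40,39,38,40,42,41,43,44,43,41,43,46,45,44,47,47,48,48,49,49,50,52,51,49,52,53,53,52,54,55,57,54,55,55,56,56,54,57
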