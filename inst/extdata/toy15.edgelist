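# toy network: 15 nodes, 19 edges
1 3
2 3
3 4
3 5
3 6
3 7
4 5
5 6
6 7
6 8
6 14
8 9
8 10
9 10
9 12
10 11
10 12
10 13
12 15
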