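Age,Feeling sad or Tearful,Irritable towards baby and partner,Trouble sleeping at night,Problems concentrating or making decision,Overeating or loss of appetite,Suicide attempt,Feeling of guilt,Problems of bonding with baby,Feeling anxious
2,1,1,3,2,2,3,2,2,1
3,2,2,1,1,3,3,1,1,1
1,3,1,3,3,1,3,2,1,2
1,1,1,2,2,2,3,2,1,1
5,3,3,2,1,3,3,2,3,2
1,1,1,3,2,2,1,3,1,2
5,1,1,3,1,1,1,1,1,1
4,3,3,3,2,2,3,3,3,2
3,3,1,3,2,1,1,2,2,1
1,2,1,1,1,1,1,1,1,1
2,3,3,2,3,3,2,1,1,2
2,2,1,1,2,2,2,2,1,1
1,1,3,2,3,1,3,2,1,1
2,2,1,1,2,1,3,3,2,1
1,2,3,1,1,3,2,2,2,1
3,3,1,2,3,2,1,3,3,2
3,2,3,2,1,1,3,2,1,1
5,2,1,1,3,3,1,1,1,1
2,3,3,2,3,2,2,1,3,2
2,2,1,2,3,2,2,2,1,1
2,1,1,1,1,1,2,1,1,1
3,3,3,3,2,3,1,1,3,2
2,2,3,1,3,2,2,1,2,2
4,1,1,1,1,1,1,3,1,1
3,3,1,1,3,1,1,3,3,1
3,3,3,3,2,3,3,3,2,2
3,1,2,2,1,1,1,2,1,1
2,1,1,3,2,2,2,1,1,1
3,1,3,2,1,1,1,3,2,1
1,3,3,3,3,2,3,3,2,2
1,2,3,1,2,3,1,1,2,1
1,2,3,3,2,2,2,2,2,2
4,1,2,2,3,1,3,1,3,2
1,2,1,2,2,2,3,1,2,1
1,3,2,1,2,1,1,3,1,1
4,2,1,3,3,2,2,2,3,2
3,1,1,3,3,2,1,2,3,1
5,2,2,3,1,3,1,3,2,2
2,1,2,1,2,1,3,1,1,1
2,2,2,2,3,3,1,2,2,2
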