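french 0.1895 -1.3033 0.3532 0.5987 1.3701 -1.3272 -0.2630 0.2005 -1.1407 0.0494
korean -0.5647 -0.2788 -0.4305 -0.8509 0.6556 0.1852 -0.9535 0.6120 -1.4592 0.1192
italian -0.0845 0.7833 -1.8480 0.7238 0.9935 0.0820 -1.6661 0.5562 0.5152 -0.0164
japanese 0.1670 -0.6333 -1.1499 -0.0150 -0.7274 1.6733 -0.2486 -0.5063 0.9581 -1.0131
mexican 0.1210 -1.6652 1.3512 -0.1912 0.1624 -1.5292 0.2995 -0.4269 -0.0531 1.0935
indian -0.2180 -2.1344 -0.0928 -0.5072 0.8472 1.9534 -0.8072 0.7834 0.5028 0.6939
cheese -0.8890 -2.4466 0.3069 -0.6934 0.0341 -0.2939 -0.9680 -1.4678 -1.6260 -0.4849
wine 0.5298 0.0352 0.2820 0.8322 1.5505 -0.6817 -0.5572 1.0110 0.2697 -0.2054
sushi 0.7213 -1.0103 -0.0306 -0.5768 -0.1422 1.4817 0.1241 -0.1730 0.4302 -1.2614
taco -0.0658 -2.2641 0.9236 -0.1005 -0.4319 -0.9499 0.0954 -0.2438 -0.4913 2.3684
curry 0.3464 -1.1405 0.3652 -0.6873 -0.6072 1.0152 -0.9573 0.0103 -0.0840 0.3507
pasta 0.6849 1.3225 -2.4319 2.2671 0.9787 -0.1869 -1.4974 0.2987 0.4343 0.0485
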