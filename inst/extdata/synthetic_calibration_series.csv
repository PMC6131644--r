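"zn_molar","fluorescence","condition"
0,136.187747223598,"synthetic_control"
5e-11,135.238400715259,"synthetic_control"
1.5e-10,134.239545018392,"synthetic_control"
5e-10,134.57256744422,"synthetic_control"
1.5e-09,138.88295867388,"synthetic_control"
5e-09,144.849144644693,"synthetic_control"
1.5e-08,161.505385290628,"synthetic_control"
5e-08,249.745930561591,"synthetic_control"
1.5e-07,696.335893455001,"synthetic_control"
2.5e-07,979.495756754251,"synthetic_control"
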