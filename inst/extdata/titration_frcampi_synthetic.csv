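"x","y","x_kind"
8.8,1.0157,"calcium"
18,1.1431,"calcium"
37.9,2.3267,"calcium"
85.4,9.2758,"calcium"
146.3,14.19,"calcium"
227.6,15.7023,"calcium"
341.5,16.1252,"calcium"
512.2,16.2498,"calcium"
796.7,16.2872,"calcium"
1365.8,16.2976,"calcium"
3073.1,16.2998,"calcium"
6487.7,16.3,"calcium"
13316.9,16.3,"calcium"
26975.3,16.3,"calcium"
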