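{"seed":42,"sizes":[50,50,50],"dichotomized":false,"generator":"R 4.3.3 Mersenne-Twister"}
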