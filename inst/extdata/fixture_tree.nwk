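(((s01:1,s02:1):1,(s03:1,s04:1):1):1,((s05:1,s06:1):1,(s07:1,s08:1):1):1);
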