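>homology5 synthetic 35-nt placeholder arm (testing only; not a real cassette sequence)
GATTACAGATTACAGATTACAGATTACAGATTACA
>homology3 synthetic 35-nt placeholder arm (testing only; not a real cassette sequence)
TGCATGCATGCATGCATGCATGCATGCATGCATGC
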