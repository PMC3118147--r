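>ath-miR159a
UUUGGAUUGAAGGGAGCUCUA
>ath-miR319a
UUGGACUGAAGGGAGCUCCCU
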