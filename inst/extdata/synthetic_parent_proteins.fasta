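>AMELX_P173_SYN synthetic surrogate parent embedding the P173/LRAP N-terminal marker peptide; not a database sequence
MPLPPHPGHPGYINFSYEVLTPLKWYQSIRPPLAPQFPMQPLTPILPELPLEAWPSTDKTQ
HAMFPMGFSMQPLSPLQSK
>AMELX_P190_SYN synthetic surrogate parent embedding the P190 marker peptide; not a database sequence
MSVQTPLIKLPPHPGHPGYINFSYEKAVGSTQDLMAWFHQPLSK
>AMBN_SYN synthetic surrogate parent embedding the ameloblastin N-terminal marker peptide; not a database sequence
MAFTLQPWLSKQPGTPGVASLSLETMRELPGFDHSVNAPAWTK
>ENAM_SYN synthetic surrogate parent embedding the enamelin 32 kDa marker peptide; not a database sequence
MGSLLTAFWSKGYHGFGGRPPYYSEEMFEQDFEKPKTVDGLEHWAQSPLFK
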