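# Synthetic HLA pseudo-sequence fixture (randomly generated 34-mers).
# Not NetMHCpan data; for testing only.
HLA-A*01:01	HTYQKGGPNCRTFNNTNECPQMKKQFECPQRQRK
HLA-A*02:01	DCCHESYECQQSQTELNTGCIDKIPECGMNSVRM
HLA-A*11:01	FHFRGWTMENAQTCRLKCCNMTFKPATFAYPVHY
HLA-A*24:02	QYWYPCMCMRKTDGVYLVVLKPFGGIHDFQGMQA
HLA-B*07:02	QEYCVYQHMAHNAMHVMSIEQIMMGNWGWWNDIQ
HLA-B*08:01	DMNEMYMCEVVLELGQCMASGHCIAIEWAALAQG
HLA-B*57:01	SRRGEEFKVNYSWEDESVICMAKRWTTSIMMCND
HLA-C*04:01	ERMHDAGTSIHGSDRCGCACVFPLGAEWVDHKAP
HLA-C*07:01	NQQHEQYMKGADPRRMKIVHWGTPQEAGSDYLRR
HLA-C*07:02	LDLTVDGCACHWKEIMAINYLHIYYGFIMDQRMK
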