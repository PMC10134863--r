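# Per-genus marker exclusion lists for Jingweiarchaeales/Parvarchaeales
# genome QC. Each [block] lists the universal archaeal CheckM1 markers
# that are missing from every genome of that genus and are therefore
# removed from its expected marker set. The [shared] block lists the
# markers absent across all lineages of both orders.
[shared]
PF01849.13
PF01912.13
PF01922.12
PF04127.10
PF05221.12
PF06026.9
TIGR00336
TIGR00670
TIGR01213
[Jingweiarchaeum]
PF01849.13
PF01912.13
PF01922.12
PF04127.10
PF05221.12
PF06026.9
TIGR00336
TIGR00670
TIGR01213
[Haiyanarchaeum]
PF00398.15
TIGR02076
PF06418.9
PF01725.11
PF04019.7
TIGR00270
TIGR00057
PF00832.15
TIGR00549
PF01982.11
PF00958.17
PF01864.12
PF01849.13
PF01912.13
TIGR00670
PF06026.9
PF01922.12
PF04127.10
PF05221.12
TIGR00336
TIGR01213
[Rehaiarchaeum]
PF00900.15
PF00466.15
TIGR02338
PF04010.8
TIGR00422
TIGR00344
PF06418.9
PF01282.14
PF01725.11
PF04019.7
PF00831.18
TIGR00057
TIGR03677
TIGR00432
PF13685.1
PF00832.15
TIGR00549
PF01982.11
PF00958.17
PF01864.12
PF01849.13
PF01912.13
TIGR00670
PF06026.9
PF01922.12
PF04127.10
PF05221.12
TIGR00336
TIGR01213
[Acidifodinimicrobium]
PF02005.11
PF08071.7
TIGR02076
PF01725.11
PF04019.7
PF00831.18
TIGR00057
TIGR03677
TIGR00432
PF13685.1
PF00832.15
TIGR00549
PF01982.11
PF00958.17
PF01864.12
PF01849.13
PF01912.13
TIGR00670
PF06026.9
PF01922.12
PF04127.10
PF05221.12
TIGR00336
TIGR01213
[Parvarchaeum]
TIGR03677
TIGR00432
PF13685.1
PF00832.15
TIGR00549
PF01982.11
PF00958.17
PF01864.12
PF01849.13
PF01912.13
TIGR00670
PF06026.9
PF01922.12
PF04127.10
PF05221.12
TIGR00336
TIGR01213
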