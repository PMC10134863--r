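# Synthetic 149-id archaeal single-copy marker set.
# Contains the 34 distinct published genus-exclusion accessions for
# Jingweiarchaeales/Parvarchaeales plus 115 synthetic filler ids
# (SYNMARK###). The full curated 149-marker archaeal roster is not
# redistributed here; replace this file with your own list for real QC.
PF00398.15
PF00466.15
PF00831.18
PF00832.15
PF00900.15
PF00958.17
PF01282.14
PF01725.11
PF01849.13
PF01864.12
PF01912.13
PF01922.12
PF01982.11
PF02005.11
PF04010.8
PF04019.7
PF04127.10
PF05221.12
PF06026.9
PF06418.9
PF08071.7
PF13685.1
TIGR00057
TIGR00270
TIGR00336
TIGR00344
TIGR00422
TIGR00432
TIGR00549
TIGR00670
TIGR01213
TIGR02076
TIGR02338
TIGR03677
SYNMARK001
SYNMARK002
SYNMARK003
SYNMARK004
SYNMARK005
SYNMARK006
SYNMARK007
SYNMARK008
SYNMARK009
SYNMARK010
SYNMARK011
SYNMARK012
SYNMARK013
SYNMARK014
SYNMARK015
SYNMARK016
SYNMARK017
SYNMARK018
SYNMARK019
SYNMARK020
SYNMARK021
SYNMARK022
SYNMARK023
SYNMARK024
SYNMARK025
SYNMARK026
SYNMARK027
SYNMARK028
SYNMARK029
SYNMARK030
SYNMARK031
SYNMARK032
SYNMARK033
SYNMARK034
SYNMARK035
SYNMARK036
SYNMARK037
SYNMARK038
SYNMARK039
SYNMARK040
SYNMARK041
SYNMARK042
SYNMARK043
SYNMARK044
SYNMARK045
SYNMARK046
SYNMARK047
SYNMARK048
SYNMARK049
SYNMARK050
SYNMARK051
SYNMARK052
SYNMARK053
SYNMARK054
SYNMARK055
SYNMARK056
SYNMARK057
SYNMARK058
SYNMARK059
SYNMARK060
SYNMARK061
SYNMARK062
SYNMARK063
SYNMARK064
SYNMARK065
SYNMARK066
SYNMARK067
SYNMARK068
SYNMARK069
SYNMARK070
SYNMARK071
SYNMARK072
SYNMARK073
SYNMARK074
SYNMARK075
SYNMARK076
SYNMARK077
SYNMARK078
SYNMARK079
SYNMARK080
SYNMARK081
SYNMARK082
SYNMARK083
SYNMARK084
SYNMARK085
SYNMARK086
SYNMARK087
SYNMARK088
SYNMARK089
SYNMARK090
SYNMARK091
SYNMARK092
SYNMARK093
SYNMARK094
SYNMARK095
SYNMARK096
SYNMARK097
SYNMARK098
SYNMARK099
SYNMARK100
SYNMARK101
SYNMARK102
SYNMARK103
SYNMARK104
SYNMARK105
SYNMARK106
SYNMARK107
SYNMARK108
SYNMARK109
SYNMARK110
SYNMARK111
SYNMARK112
SYNMARK113
SYNMARK114
SYNMARK115
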