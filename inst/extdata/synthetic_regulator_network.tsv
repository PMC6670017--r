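regulator	target
REG_A	GENE0001
REG_A	GENE0002
REG_A	GENE0003
REG_A	GENE0004
REG_A	GENE0005
REG_A	GENE0006
REG_A	GENE0007
REG_A	GENE0008
REG_A	GENE0009
REG_A	GENE0010
REG_A	GENE0011
REG_A	GENE0012
REG_A	GENE0013
REG_A	GENE0014
REG_A	GENE0015
REG_A	GENE0016
REG_A	GENE0017
REG_A	GENE0018
REG_A	GENE0019
REG_A	GENE0020
REG_A	GENE0021
REG_A	GENE0022
REG_A	GENE0023
REG_A	GENE0024
REG_A	GENE0025
REG_B	GENE0041
REG_B	GENE0042
REG_B	GENE0043
REG_B	GENE0044
REG_B	GENE0045
REG_B	GENE0046
REG_B	GENE0047
REG_B	GENE0048
REG_B	GENE0049
REG_B	GENE0050
REG_B	GENE0051
REG_B	GENE0052
REG_B	GENE0053
REG_B	GENE0054
REG_B	GENE0055
REG_B	GENE0056
REG_B	GENE0057
REG_B	GENE0058
REG_B	GENE0059
REG_B	GENE0060
REG_B	GENE0061
REG_B	GENE0062
REG_B	GENE0063
REG_B	GENE0064
REG_B	GENE0065
REG_C	GENE0081
REG_C	GENE0082
REG_C	GENE0083
REG_C	GENE0084
REG_C	GENE0085
REG_C	GENE0086
REG_C	GENE0087
REG_C	GENE0088
REG_C	GENE0089
REG_C	GENE0090
REG_C	GENE0091
REG_C	GENE0092
REG_C	GENE0093
REG_C	GENE0094
REG_C	GENE0095
REG_C	GENE0096
REG_C	GENE0097
REG_C	GENE0098
REG_C	GENE0099
REG_C	GENE0100
REG_C	GENE0101
REG_C	GENE0102
REG_C	GENE0103
REG_C	GENE0104
REG_C	GENE0105
REG_NULL	GENE0956
REG_NULL	GENE0799
REG_NULL	GENE0249
REG_NULL	GENE0629
REG_NULL	GENE0591
REG_NULL	GENE0419
REG_NULL	GENE0390
REG_NULL	GENE0307
REG_NULL	GENE0427
REG_NULL	GENE0717
REG_NULL	GENE0397
REG_NULL	GENE0614
REG_NULL	GENE0450
REG_NULL	GENE0895
REG_NULL	GENE0961
REG_NULL	GENE0711
REG_NULL	GENE0845
REG_NULL	GENE0157
REG_NULL	GENE0225
REG_NULL	GENE0849
REG_NULL	GENE0605
REG_NULL	GENE0797
REG_NULL	GENE0922
REG_NULL	GENE0502
REG_NULL	GENE0721
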