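posture,expected_group
UNK LSP S-LSP,UserDefined
UNK LSP S-U45,UserDefined
UNK S-LLS LSP,UserDefined
UNK U90 S-U90,UserDefined
UNK U90 U45 LLS S-U90,UserDefined
UNK,Unknown
UNK LSP,Unknown
,Unknown
U90 U45,Upright
U90 U45 WLK,Upright
U90 U45 LLS,Upright
U90 U45 LLS WLK,Upright
U45 LSP WLK,Upright
U45,Reclined
U45 LLS,Reclined
U45 LPR,Reclined
U45 LPR LRS,Reclined
U45 LRS,Reclined
U45 LRS LLS,Reclined
U45 LSP,Reclined
LLS,Lying
LPR,Lying
LPR LLS,Lying
LRS,Lying
LRS LLS,Lying
LSP,Lying
LSP LRS,Lying
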