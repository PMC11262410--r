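# Synthetic stand-in for the study's predicted protrusion-localized gene
# list. The eleven real FBgn identifiers below are the query-panel genes the
# published membership table marks as predicted; the SYNPAD identifiers are
# synthetic padding representing the remainder of the predicted list, which
# is not redistributable here. Suitable only for the worked membership
# example, not for biological reuse.
FBgn0010238
FBgn0286818
FBgn0015777
FBgn0264078
FBgn0010215
FBgn0005671
FBgn0002921
FBgn0264975
FBgn0035533
FBgn0001145
FBgn0013733
SYNPAD0001
SYNPAD0002
SYNPAD0003
SYNPAD0004
SYNPAD0005
SYNPAD0006
SYNPAD0007
SYNPAD0008
SYNPAD0009
SYNPAD0010
SYNPAD0011
SYNPAD0012
SYNPAD0013
SYNPAD0014
SYNPAD0015
SYNPAD0016
SYNPAD0017
SYNPAD0018
SYNPAD0019
SYNPAD0020
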