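# Literature reference panel for Kawasaki disease classification.
# One gene symbol per line; '#' starts a comment.
TLR6
COPB2
FCGR2A
CD40
BLK
CASP3
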