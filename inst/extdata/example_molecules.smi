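# small demonstration library: named natural products, simple controls,
# a salt and an enantiomer pair
CCO FIX01
c1ccccc1 FIX02
C1=CC(=C(C=C1C2=C(C(=O)C3=C(C=C(C=C3O2)O)O)O)O)O FIX03
C1=CC(=CC=C1C2=COC3=CC(=CC(=C3C2=O)O)O)O FIX04
C[C@@]12[C@@H]([C@@H](C[C@H](O1)N3C4=CC=CC=C4C5=C6C(=C7C8=CC=CC=C8N2C7=C53)CNC6=O)NC)OC FIX05
OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O FIX06
Cn1cnc2c1c(=O)n(C)c(=O)n2C FIX07
CC(=O)Oc1ccccc1C(=O)O FIX08
CC(C)Cc1ccc(cc1)C(C)C(=O)O FIX09
c1ccc2ccccc2c1 FIX10
C[C@@H](N)C(=O)O FIX11
C[C@H](N)C(=O)O FIX12
CC(=O)[O-].[Na+] FIX13
OCC FIX14
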