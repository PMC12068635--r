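code,label,endpoint_group
8542,Bilateral simple mastectomy,breast
8544,Bilateral extended simple mastectomy,breast
8546,Bilateral radical mastectomy,breast
8548,Bilateral extended radical mastectomy,breast
683,Subtotal abdominal hysterectomy,uterus
684,Total abdominal hysterectomy,uterus
685,Vaginal hysterectomy,uterus
686,Radical abdominal hysterectomy,uterus
687,Radical vaginal hysterectomy,uterus
689,Other and unspecified hysterectomy,uterus
6551,Removal of both ovaries at same operative episode,ovary
6553,Removal of remaining ovary,ovary
6561,Removal of both ovaries and tubes at same operative episode,ovary
6563,Removal of remaining ovary and tube,ovary
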