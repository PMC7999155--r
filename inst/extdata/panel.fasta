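>HSA_SYN HSA-derived mature albumin model sequence (synthetic panel)
DAHKSEVAHRFKDLGEENFKALVLIAFAQYLQQCPFEDHVKLVNEVTEFAKTCVADESAE
NCDKSLHTLFGDKLCTVATLRETYGEMADCCAKQEPERNECFLQHKDDNPNLPRLVRPEV
DVMCTAFHDNEETFLKKYLYEIARRHPYFYAPELLFFAKRYKAAFTECCQAADKAACLLP
KLDELRDEGKASSAKQRLKCASLQKFGERAFKAWAVARLSQRFPKAEFAEVSKLVTDLTK
VHTECCHGDLLECADDRADLAKYICENQDSISSKLKECCEKPLLEKSHCIAEVENDEMPA
DLPSLAADFVESKDVCKNYAEAKDVFLGMFLYEYARRHPDYSVVLLLRLAKTYETTLEKC
CAAADPHECYAKVFDEFKPLVEEPQNLIKQNCELFEQLGEYKFQNALLVRYTKKVPQVST
PTLVEVSRNLGKVGSKCCKHPEAKRMPCAEDYLSVVLNQLCVLHEKTPVSDRVTKCCTES
LVNRRPCFSALEVDETYVPKEFNAETFTFHADICTLSEKERQIKKQTALVELVKHKPKAT
KEQLKAVMDDFAAFVEKCCKADDKETCFAEEGKKLVAASQAALGL
>SYNBG1 synthetic plasma-background protein 1
MKTAYEFGHLNDWSRAVGELTPQKFNDGSAVLYTRGEILNPAWDKSTVFEQLMGNRHDYA
TPLVKSENWFGDLIRTQAGVSEK
>SYNBG2 synthetic plasma-background protein 2 (avidin-sticky HPY motif)
MGSDLKAEHPYFYTPELRNVSDQWAGTKLFEHPYAVNDGSRQTLMEKWDNAPGVYSELHR
TKFAQGDNLVSPEWTR
>SYNBG3 synthetic plasma-background protein 3
MAVNLDEKGTWFSQRPLHEYVDNAGSKMTLFEDRWQAGNVSYPLEKHTDSGAFVNQRLEW
GDYSATKPMNVDLGFER
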