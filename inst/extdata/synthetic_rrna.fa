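>18S synthetic mature rRNA (random sequence, published modified residues forced)
UGUACCGUUAGCAGGUCGUAUUUGGGCAUCAUGAGAACAACCUAACUGGUACACUUCGGCACCCUAGCCU
GCCGUAGAUAACGUCCAGCUUCAGGUCCAUCGGUAAAUACUGAGAUCCAUUCAUAUGGGGGAUUAGCCCU
CUUCAAAUGGAGGUGGCGGUUCGGUGACUCACACAAGAGGCGUGAUCGUCGGUAUUUCGCUAGAUUACCU
UGUUGACCUCUCAUUCUUAAAUUGGAAGAGAUUCGAAACCUCAAACAUCCACGUGUGACGGUGGUAAUUC
AGUUCAAGUUUAGCGUACAAGUGCAAUUGCCUGGGGAAUUAGAGUCUAAAUAGUAACAAAACGAUCUGCA
AACUGGUCCCCGCAAGGGAUUCCCCCACAGUGAUUUGUUAGACCUCAAACGCGGGGGUGCGGAAGGAGUG
CCUAUUAUUAUGUAUGUGCAUGAAUCGAGAUGGUAGCCGGGUGAUGCGACACCCCGGUACGCGCCGUGGU
GACGAUAGCUACCCAGCGGGACCAUGGAUACGGGGGCCGCCCAAGUGGUGGUGACUAGACCUUUCAGUGA
UUCAAUGUUAGCCUGACGUAGCUCGGUAUAAUCCCUAGGUCUUCGCGUCGGUUCUAUAUGCGGGGCCACU
UACUUACUUUACGGGAGCCAAUAACGUGACCUGUGCUAGACGCAUCCUUAUUACUGUUAAAAGACGUACU
GUCUCUAUGUCGCCUGUCUUCCAAAUUUAUUUGGAAGGAGAAAUCGCCUGAUGAUGACAGGCCAGUCUGC
ACCAACCUGGAGGCUUAAGCCCCCUGUGGUGGACACUGACGAUAGAUAGUGGUCUAAGCGCUGGUGGUGA
GUUAGCGGUUCGUGUGUCGUAGAGCAGUAGUGUUUGAUACCCCAAAGAUCAUUAAUUUGCUACUACACUA
CGCCGAUCCGUAACGUAUUGUAAUGAUAGUAAAGAGACUGCGGACAGCACACUGGGGUAAUGGGAGGCCA
AACAAGACCAACGUGCGGACUGACAGCAGGUUGCGGGCUCAGAAGGGUCUUCUAGCACAGCAAGAUAGGU
CUUGGGCACAGGGAUAGGCGUAGCAAGUGGACCGAAUCACACUUCGCGUCAGUAGUUCUUGAGAAUCUUG
GUACCCGGGCCUCGCUGAUUCCACCUUCUCAAAGGUGGGAAGCUCAUCGCGCGAGUUCCCUGUAACACUC
CGAAGUCGCGUGUGUCGUACUCCAUAUAACAGAGUAAGCAACCGUAGUCACUUGUCCCAUGAAUUCGCAU
UGGAACCAGCGCAACAAUCUCCUAUGUACGCAGACAUCAAGCAGGGUUGUUCUAAUCGCCGGAGAGCAGG
CGUCCUGCCGUCAGAUGCUGCUUUGACGGCCCCGGCCCGAAUGGGUAACGAUAACCCGAACGGUUUAACU
UCCAUUACAGCUGCUCAGAUAUUUAUAAUCAGGCAAAAGCGUAACAGGAUACAAUGCUGGACAUGAUUAG
GUGCAUCUGUCGACGGGCCAGAGCAUUUGGCGAUCGGGGUCAGCUAUACUUCACAGUGUAUCCGCCGCUU
GUAAUUCGAAAGGUGCGCAGGUAAUUGAUGACCCGAAAAAAUGGGGCAGGUGCCAAGCGAUAACCCGUAC
UUGGAGCUGUUCCACACCGGCCCGGUACGCCUCCGGGGUCGUAGGCGCCUUUGAAGAAUUAUGUAGCCUC
AACUGAUUAAGACCGGAUUGAUUCAUUUUCUGAAGUAUUUAAACGUUAGGGGACAGUUGAUCUUGCGCGG
CCGACAAGCACCGUCGGAUGAUAAGUGCGGAAGGAAGGACGACGUGUUGAUGACAGAUGCGGUGAAGUUU
UACCAACCCAGCAUGUGAUCAUAGUCAACCUCGUGCCUAUUUUACAUCA
>28S synthetic mature rRNA (random sequence, published modified residues forced)
ACAUUAGUGACGAAUUGAAAUGGAGAUCCCAUCCCAGCUCAAAACUAUGUAAUACGGGUCGUCGAUGUGA
CCAGCAGAACGGACGCAACCCUAUUGAUUGCGGGCUUCAAAAGCUGUUAAGGGGCGCACUUAGGGGACGG
UUCCAUCAUGACCGCGAAAAACCUGCCCGUGUGGUCUUUGCGAGUAAAACAAGACCUACUGGAGCGGAGU
CAGGGGGCCAUAUCGUGCACUGACGGACACUCGAGGUCGAGGGUAUUGACUAGCCGCAAAUCCAACUUGA
AAAUCUCGUAGCUCCAUAGAUUUCACGCCUUCCGUUUCACGGUAAAGUUCAAUAGUCCCUGCUGGUCGAA
GGUAUGACUCCGAGUGUUCCGAUUAGAUAGUGCGUAGCAGUCCUCUACAGGCUUUGAGAGCCAGAACGCG
UGUCGUCCGCCUUUUUUAACGGGCCUGGCCUUUCAGCAAGCGCAGCUCGUGUCGGUUCCAAUUUAGCGAA
CCCCGGUGGUGUCCGUGGCACUCCCGACGCCAGAAUUAAUGUCUUCCACGCGCGCGGUCGCCAAUACGCU
CUCGGGAGAGGUAAGAUCUGGUUGUCCAGGCCCACUGGAGGGAUCUAGAAGUAAUGGCGAUUCUAAUUUU
UAGCGAUGCUACGACCAACGAAUGACGGUCGUUACGGCGCAGCACAGGUCAGACGAUGGGGUAUGACUCC
CGGCGAAUAAAGUCGCGUAUGCUACGGCAAGCAGUUCGAAAGGACUACGACCUCUUAUCUGGCGAAGGGA
GCUCGUGGGGCACCUAUCACCGCAUGUAUCGCAUAGUCGCGAGAAGACAAUGUUGGGGUUAGUAAUCCAA
GUUGGAUAUACCUAUACAUGGACGAAGUAAUCCGCUCAGGAACUCAGAUGAAGGCAUCAAGGUCAUUGUA
UCGUAAUCGAAGGUUUGGCGUGAUGACGCGUCGAAAAGGUUUAGAAGGCCCAACGGGCAUAGAGGUUCAA
UCCCUGGCCCGGCAAAGGAGGACGUGAGUGGCACCAUCACUGGUCUAUGCCGUCAGUAAAGCAUCCACGG
CUCGGGCCAAACAGCCGUCCGUGAGUGUCCGAACUUGUAGCUCGACCCCCAUCGCUGGCGUCUUAUGGAC
GCCGCACUCACGGAGGUUUCGCUGAGGCGCAAUGACGAUUCGAGUUUAAGGCAGCACUAGGGAUGCGCCA
ACGCCGCUUUAGGCUGCAGACGGGGGGUAAAGUGUAUAAGGACGCGUUCCGGCGCCUACCAUCAGUGAUG
UAAAUCUGUGUCAAUGCAGUUCAGAGGGACACUCCUGUCGGCGCCCUAGAUGAAAAAUAUCGAUGGUACA
UAAAUAGCGCCUGAGAUUCUACUCUAAGCAAGGGACUAUAACUUGUCAAUACGGGACUGUUGUGAAGUGA
CUCUCCCAAAAUGCUCAGAGUGGGCGUUAAUUCCUUAUCAGACUGCUAGAGUGUACAAAGGUCUCUUAGC
UCCUAAUGAGCUCGCUUGACCCAGCUGCGGCAUUCCGAGAAAGGAAGAAACGCAACAAAAUAACUUAGUG
AUAGCGCCACGCAGGUUCAGCCCAGCAGCAUUGUCUGGCGGUCGUUGGCGGAGCGUUCUGAACAAAACCU
ACGAAAAUGAUGCACAUCGUUGGCUCCCUAAUCAUGAUAGUCAAAAAGGCUGCGGUUCAUUUUCCACUGC
CUAGGCGUGGUCACUCGUAAAAGCGUCCUGAUGUGUUUUAAACUAUGGAUAAAUGUAGCGUUCAUGUGCA
CAUCCGUUGCUAAUGCACCGCUAAUGGCUUGACGGCGAUCAGCGCGCCAAGCCAGGCUAUUCAUACUGAU
GGGGGUUUUUUGUGCAAUGUGAUUCCGCUUGUGCGAUUGCUUUAUCCAGAUACCCGCCGCCAGAGUGCCG
UGAUGAUCACCCUUAGCCCCCUAUGAGACAAUCGUCGGAUCCAGCGUAGUGAUGUACGGACUGAGAUAAU
ACGAAGACUGUUAAGAUAAGAGCACGAUUACUCUCCAGAAAGAAGACAGCUAGCUCUUCCUGGAUCGAAU
ACAUAUAGCCCCUUCGCUUGUCCUCUCUUAGAAACAACGUGAGCCCGUCGUCUCAAGAAUCAUGUGGGAC
CAUGAGCGCAGCCCCAAUGGUUAUCAGCCUCUACUAGUAGAGAGAGGCACUGGAUACACCCAAAGCUUAC
AUACAUGCCGUGUGGGCGAGCGAUGGCAAACGGGACAGUGACCGAAAAGAAGCCCUCGCAGUGGUUAACC
AUCUGUGCACCCCGAGGAGCGGGUAUACAACAGGAACCGACGCCAGGUGGCCUAAAGGCAGUUGGGAUCU
GUCCACGGAAAUGUACAGAAUUCGGCGGUUUUACUCUGCAUGGGGUUACGCCUUCAGCCCUUCUGGCUAA
GAGCCACGCGGAAAAACGCCAGGCCGCGCUCAUCCAACCACUUCGCUGGCUUGUAGAGAUAUAGAGGGCG
ACACAUCCAGCCCCAAUAUCUGGCCGCGCACGGCGGUCACAGGAACCUAGAUUGUGUUUGAAAUCAGCAU
GGAACGGCAAAAAUUGCAUCGACCCGGUUUGAACAGGAACGCAGUGCAGAACGUUAGUGAAGCAUAUGUA
AAAACUGCAGCGCAUCAAGAAGGAUCAGACAGGAAGCAGAGGCUUUCCCGCAACACAAUUCGGGAACACU
CAACACAAACACCACACCACCAGCAAAAACCGCUAAGAUCGGCAGGCGUGCACAGCGCCCCCGCGGAUCG
CGCUUGUUAUAUCUCGAAGGCUUUAUGGAGCACUGAAAUAGCAAAAGAAAGAAUGAAAAGGAGUGUUAAA
UGGUACACCUAUGCGUUUGAGCCGUUUGAGCGUUAGUUUCGUUCGGCUAAGCACAGCGGCCCCCGACCAG
UCCUUGUUGCCUCCCACGUAUCAGUGAUAGGCCCCGGCAACACCCGAACGGUAAGUAUCCCCGCCACUGA
ACUGGUGCAUGAGGCAAGGACGGGCUCACCCAAAGACACAGAUAUGUUACGGGUUGAGUCAAACGAUGCU
CGCCUCACUAGCGCAAACCAGAACUAGUCCGUGGCCGGUAAACCGACUUCGUCGGAGGGGACUUGGGCAU
UUGGCAUUUUGAGAGCACUAUAAGCGGUACGUAGGUUGGUAAACAGGAAUGUAGGGGAACAGUCCACGGU
GGACAAGCCAUCUAUUGCGCUCAAGCGACUCUCUGCUCCCCCGCAAAAGCAAGGCGGUUGUCUAGGGAAC
GGCCUGUGCGCAAAGCGGGAAUUGCGGGGCCGACCACCCUCCGUUAGCACAGCCGGGGGUAGCUCUAAUG
GCUACCAGCGCGGAACCCAGAAAGUAGGAGUACGGCGACAGCUAAGAAUGUGCUUGGCUUGGGGGUAGAA
CUAACUGGUGCUAACUGUGGUUUCAUGAUCGAGGAAGCCACUUCCCCACACUGACCCACCGCGACUGUGC
GUAGAAGUACAAGGCGAGUUGCUGAUCCUAGAGUUUUUGCAUUGCCCGAGUGCAUUUGUCACGAUAUAGA
GCGUUCGAGUGGACCGUUUCGAAGAACUCCAACAACUAAGGAGUAGAUCAGCUUGAAACUGGUGGGCUCG
UUUACUUGGUUUUUCCACGGCGUUCGUCGUCCGUCUCGGUUAGAAUGCUUAGAUUGGGGUUAAACUCAAG
CACGUAGGAUUAGGCCCCGCCGCGGUACUCAGAGUCACACCCGGCCCGCUGGGGCCGCGUUGAGCUAUGA
AGGCUUGGUUAGAAACGUAAUAGUCAACCCCAAAGGGUCGAUCAUCAGACGUGAUCUAGCUCGAGUAAAG
CUUUCAUGUCCUUCGCCUACACUGUACUUUGAACCCCACGGUAAACAACAUUUUUGUAUCAGGCGGUCUC
CACGCCGGGGAGGCAUAUCCUGUACGUUGCCUGUUAGGCGUGUAAUAAGGAAUUCGCAUCCAAGUGUGCC
CCUGUGCGGAGUAAUAGGCGGGUCCACAGGAUGCAGGUGUUAACAGAUUUAUGUCACGAGGUGAUGUUCU
CGGUGAGUUUCGAAGUCCUGCAAAAUCGAGCUUAUGAUAGGCGACAAGUGUGCCUAAGCCAUGCCUUCUC
GGCCCCAAAGAACAACUGGUAGAAGCUACGAGGGCUAGAGAGUAUGCAUGUUGUAGUGAUGGAAACGAGG
AGCAGAUAAGUCCAACUGUGCCGUUGUCCUUGCAGCGGUGCCGACAGGCUUAGGAACUGCAGAAGACAAU
UCUUUAAGUGAUGCGUAAAUUUGGAAAUCAGAACCGAAACUAGGGUGUUAUCUUAUACCAUUGUUUUGGU
CAUACUUGUCUUUAGGUCGUAGGAGGGUCCAAUACCACCUCUCAUCGCUACGCUUACCUCGUGUAAGCUG
UAAUAACUUGUUUAAGAGGGCGGCCCCACUUCCGGCUCCAUUGUCCCUUCGGGACUGUAACAAGAAGUAC
UGGGACGCGUCGAUAAUGAUACUGAUCCUCGUAUGGGAGCAGGGACAGGCCAUAAGCGACUAAACGAGUC
UAAUUGGAACACUUGGGAUAUUGGGGCAUAGCAUUAGGGGCUUUGGCCAUGUUAAUAAGUGGGCCCUUAG
AAGGGGGCAGGACGAACCGAAAUUUUACUUUAGCUAACGUGUCACCGUCGCGAGAGUCGGGGAGAUUUUG
GCGCGUGACCCCGACUGACGCCGGACCGCGCAUUUAGCAAUAAUCCGGAGGCUAUAGGGAUAUUAGGCGU
UUGUUGAAACAGUGACAUGCUCUAUGAUGGACGGGCGGGACUUAUGUCCUCAGCGAGACAUAGUCUAGGG
GAUGACUCAUUCUCUGUAGGAUUUGUGCAGCCAGGUAGGCUUAAUAGGGCAGGGGGGGGCGUGCCACUUU
GCCCACAGGGGAAGGGCUCUAUCCUGUCCAUCGGUCUCAAGUUAUGCCUCAGGGACACCAGAGCCGCACG
GCUGAAUCCGCUGUAAAUCCGCGGCGACCACCGACGGUGGAGGGGCCGGCGUAUAAAAAGUAUGAAGGAA
ACUUACCUCCCGCCGGCCUGGUGAGUCUAAUCAGUGGAGUCGGGUGUGGCACACGAAUGUAUGGGCAACU
GUGACGGACAGCCGAGCAGCCGAAGUGCAA
>5.8S synthetic mature rRNA (random sequence, published modified residues forced)
AAGUAAAGGGUCAUGUGCUCAAUCUCAAAGACUCUAAAGCGAGAUGGUGGUAAUUGUCGGAUGAGACUUA
UGUUGUUUGUUCCCCUAAGGGCAUGGCUAUCCCCGCUCCGAAAGAUACUCCAACACUGAGGAAAGUCUUA
GUGGCGCCACCAUCAGG
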