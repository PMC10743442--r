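LOCUS       SYNPHAGE               360 bp    DNA     linear   PHG 01-JAN-2026
DEFINITION  Synthetic mini phage genome for parser tests (not a real accession).
ACCESSION   SYNPHAGE
FEATURES             Location/Qualifiers
     source          1..360
     CDS             4..63
                     /product="portal protein"
     CDS             complement(101..157)
                     /product="large terminase subunit"
     CDS             join(200..220,224..250)
                     /product="hypothetical joined protein"
ORIGIN
        1 cggatgcaga acactgggaa tcagcagacg gttgatgact ttgacgaatt agactcctcc
       61 taaatcgtcc ctgtcgatcg aattcgtttc ctaccatctg ttatccgctt ccaccaacgg
      121 aagctccggc gcgacctaac tgtaatgctg gggacatcta aatatgcgtg agctctacta
      181 catcggtagt cgtcagccta tgaaaccgtc tcgaaactct aggaaaggcc ttatcccgtc
      241 gcggctgtaa aatctaactc ttgtgaagat atgtcaacca tctaaagggg aaaaggcaag
      301 aggggcgcgg gtcccagagg caggcgcact gatctcttga ttgtgccact cggtgcctct
//
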