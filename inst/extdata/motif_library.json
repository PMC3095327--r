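[
  {"name": "ARR1AT", "iupac": "NGATT", "response": "Cytokinines", "source": "table1"},
  {"name": "CIACADIANLELHC", "iupac": "CAANNNNATC", "response": "Circadian expression", "source": "table1"},
  {"name": "DOFCOREZM", "iupac": "AAAG", "response": "C-metabolism, leaf", "source": "table1"},
  {"name": "EBOXBNNAPA", "iupac": "CANNTG", "response": "Light, ABA, seeds", "source": "table1"},
  {"name": "EECCRCAH1", "iupac": "GANTTNC", "response": "CO2-responsive", "source": "table1"},
  {"name": "GATABOX", "iupac": "GATA", "response": "Light, leaf, shoot", "source": "table1"},
  {"name": "GT1CONSENSUS", "iupac": "GRWAAW", "response": "Light, leaf, shoot", "source": "table1"},
  {"name": "GTGANTG10", "iupac": "GTGA", "response": "Pollen", "source": "table1"},
  {"name": "IBOXCORE", "iupac": "GATAA", "response": "Light, leaf, shoot", "source": "table1"},
  {"name": "MYBST1", "iupac": "GGATA", "response": "Myb trans activator", "source": "table1"},
  {"name": "MYCCONSENSUSAT", "iupac": "CANNTG", "response": "ABA, abiotic stress", "source": "table1"},
  {"name": "PYRIMIDINEBOXOSRAMY1A", "iupac": "CCTTTT", "response": "Sugar repression, seeds", "source": "table1"},
  {"name": "POLLEN1LELAT52", "iupac": "AGAAA", "response": "Pollen", "source": "table1"},
  {"name": "RAV1AAT", "iupac": "CAACA", "response": "Root, rosette leaves", "source": "table1"},
  {"name": "ROOTMOTIFTAPOX1", "iupac": "ATATT", "response": "Root", "source": "table1"},
  {"name": "SEF4MOTIFGM7S", "iupac": "RTTTTTR", "response": "Seed, storage protein", "source": "table1"},
  {"name": "WBOXATNPR1", "iupac": "TTGAC", "response": "Disease resistance", "source": "table1"},
  {"name": "WBOXHVISO1", "iupac": "TGACT", "response": "Sugar, SUSIBA2", "source": "table1"},
  {"name": "WBOXNTERF3", "iupac": "TGACY", "response": "Wounding, ERF3", "source": "table1"},
  {"name": "WRKY71OS", "iupac": "TGAC", "response": "GA repressor, ABA", "source": "table1"},
  {"name": "ABREZMRAB28", "iupac": "CCACGTGG", "response": "Drought, ABA", "source": "table2"},
  {"name": "CRTDREHVCBF2", "iupac": "GTCGAC", "response": "Cold, drought", "source": "table2"},
  {"name": "GARE2OSREP1", "iupac": "TAACGTA", "response": "GA, germination", "source": "table2"},
  {"name": "GBOX10NT", "iupac": "GCCACGTGCC", "response": "Leaf, root, flower, pollen", "source": "table2"},
  {"name": "GBOXLERNCS", "iupac": "MCACGTGGC", "response": "Light, overlap ABA", "source": "table2"},
  {"name": "LREBOXIIPCCHS1", "iupac": "TCCACGTGGC", "response": "Cold, drought, ABA", "source": "table2"},
  {"name": "MYBCOREATCYCB1", "iupac": "AACGG", "response": "Cell cycle, cyclin", "source": "table2"},
  {"name": "NONAMERMOTIFATH3H4", "iupac": "CATCCAACG", "response": "Meristem", "source": "table2"},
  {"name": "ZDNAFORMINGATCAB1", "iupac": "ATACGTGT", "response": "Light, leaf, shoot", "source": "table2"},
  {"name": "SBOX", "iupac": "CACCTCCA", "response": "Sugar, ABA", "source": "text"}
]
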