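taxon	lineage
Monosiga	Eukaryota;Choanoflagellida;Codonosigidae
Salpingoeca	Eukaryota;Choanoflagellida;Salpingoecidae
Homo	Eukaryota;Metazoa;Chordata
Drosophila	Eukaryota;Metazoa;Arthropoda
Nematostella	Eukaryota;Metazoa;Cnidaria
Saccharomyces	Eukaryota;Fungi;Ascomycota
Neurospora	Eukaryota;Fungi;Ascomycota
Escherichia	Bacteria;Proteobacteria
Bacillus	Bacteria;Firmicutes
Synechococcus	Bacteria;Cyanobacteria
Sulfolobus	Archaea;Crenarchaeota
Methanococcus	Archaea;Euryarchaeota
Chlamydomonas	Eukaryota;Viridiplantae;Chlorophyta
Ostreococcus	Eukaryota;Viridiplantae;Chlorophyta
Cyanidioschyzon	Eukaryota;Rhodophyta
Thalassiosira	Eukaryota;Stramenopiles;Bacillariophyta
Phaeodactylum	Eukaryota;Stramenopiles;Bacillariophyta
Phytophthora	Eukaryota;Stramenopiles;Oomycetes
Tetrahymena	Eukaryota;Alveolata;Ciliophora
Emiliania	Eukaryota;Haptophyta
Dictyostelium	Eukaryota;Amoebozoa
Naegleria	Eukaryota;Heterolobosea
Trypanosoma	Eukaryota;Euglenozoa;Kinetoplastida
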