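>WT+NLS synthetic A1-LCD surrogate
GSGFNGRGSQFGSDGNGYKGSGNGFRGSQGSFDGNGKGYSGNGRGFSQGSDGFNGKGSGYNGRGSQFGSDGNGFKGSGNGYRGSQGSFDGNGKGFSGNGRGYSQGSDGFNGKGSGFNGRGSQYGSDGNGYKGSGKNY
>allF synthetic A1-LCD surrogate
GSGFNGRGSQFGSDGNGFKGSGNGFRGSQGSFDGNGKGFSGNGRGFSQGSDGFNGKGSGFNGRGSQFGSDGNGFKGSGNGFRGSQGSFDGNGKGFSGNGRGFSQGSDGFNGKGSGFNGRGSQFGSDGNGFKGSGKNY
>allY synthetic A1-LCD surrogate
GSGYNGRGSQYGSDGNGYKGSGNGYRGSQGSYDGNGKGYSGNGRGYSQGSDGYNGKGSGYNGRGSQYGSDGNGYKGSGNGYRGSQGSYDGNGKGYSGNGRGYSQGSDGYNGKGSGYNGRGSQYGSDGNGYKGSGKNY
>allW synthetic A1-LCD surrogate
GSGWNGRGSQWGSDGNGWKGSGNGWRGSQGSWDGNGKGWSGNGRGWSQGSDGWNGKGSGWNGRGSQWGSDGNGWKGSGNGWRGSQGSWDGNGKGWSGNGRGWSQGSDGWNGKGSGWNGRGSQWGSDGNGWKGSGKNY
>YtoW synthetic A1-LCD surrogate
GSGFNGRGSQFGSDGNGWKGSGNGFRGSQGSFDGNGKGWSGNGRGFSQGSDGFNGKGSGWNGRGSQFGSDGNGFKGSGNGWRGSQGSFDGNGKGFSGNGRGWSQGSDGFNGKGSGFNGRGSQWGSDGNGWKGSGKNY
>FtoW synthetic A1-LCD surrogate
GSGWNGRGSQWGSDGNGYKGSGNGWRGSQGSWDGNGKGYSGNGRGWSQGSDGWNGKGSGYNGRGSQWGSDGNGWKGSGNGYRGSQGSWDGNGKGWSGNGRGYSQGSDGWNGKGSGWNGRGSQYGSDGNGYKGSGKNY
>W- synthetic A1-LCD surrogate
GSGWNGRGSQGGSDGNGWKGSGNGWRGSQGSGDGNGKGWSGNGRGWSQGSDGGNGKGSGWNGRGSQWGSDGNGGKGSGNGWRGSQGSWDGNGKGGSGNGRGWSQGSDGWNGKGSGGNGRGSQWGSDGNGWKGSGKNY
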