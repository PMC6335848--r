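[Br:1][CH2:2][CH2:3][CH2:4][CH3:5].[O-:6][CH:7]([CH3:8])[CH3:9]>[Na+]>[Br-:1].[CH2:2]([CH2:3][CH2:4][CH3:5])[O:6][CH:7]([CH3:8])[CH3:9]
[OH:1][C:2](=[O:3])[c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1.[OH:10][CH2:11][CH3:12]>OS(=O)(=O)O>[OH2:1].[C:2](=[O:3])([c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1)[O:10][CH2:11][CH3:12]
[OH:1][C:2](=[O:3])[CH2:4][CH2:5][c:6]([cH:7]1)[cH:11][cH:10][cH:9][cH:8]1>>[OH:1][CH:2]=[O:3].[CH3:4][CH2:5][c:6]([cH:7]1)[cH:11][cH:10][cH:9][cH:8]1
[Br:1][CH2:2][CH2:3][CH2:4][CH3:5].[OH:6][CH2:7][CH2:8][NH2:9].[CH3:10][CH2:11][O:12][CH2:13][CH3:14]>>[Br-:1].[CH2:2]([CH2:3][CH2:4][CH3:5])[NH:9][CH2:8][CH2:7][OH:6]
[OH:1][C:2](=[O:3])[CH2:4][c:5]([cH:6]1)[cH:10][cH:9][cH:8][cH:7]1>>[OH:1][CH:2]=[O:3].[CH3:4][c:5]([cH:6]1)[cH:10][cH:9][cH:8][cH:7]1
[OH:1][C:2](=[O:3])[CH2:4][c:5]([cH:6]1)[cH:10][cH:9][cH:8][cH:7]1.[CH3:11][CH2:12][CH2:13][CH2:14][CH2:15][CH3:16]>>[OH:1][CH:2]=[O:3].[CH3:4][c:5]([cH:6]1)[cH:10][cH:9][cH:8][cH:7]1
[OH:1][C:2](=[O:3])[c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1.[OH:10][CH:11]([CH3:12])[CH3:13]>OS(=O)(=O)O>[OH2:1].[C:2](=[O:3])([c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1)[O:10][CH:11]([CH3:12])[CH3:13]
[OH:1][C:2](=[O:3])[c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1.[OH:10][CH:11]([CH3:12])[CH3:13]>OS(=O)(=O)O>[OH2:1].[C:2](=[O:3])([c:4]([cH:5]1)[cH:9][cH:8][cH:7][cH:6]1)[O:10][CH:11]([CH3:12])[CH3:13]
[Br:1][CH2:2][CH3:3].[OH:4][CH2:5][CH:6]([CH3:7])[NH2:8]>[Na+].[OH-]>[Br-:1].[CH2:2]([CH3:3])[O:4][CH2:5][CH:6]([CH3:7])[NH2:8]
[Br:1][CH2:2][CH2:3][CH2:4][CH3:5].[OH:6][CH2:7][CH2:8][NH2:9]>[Na+].[OH-]>[Br-:1].[CH2:2]([CH2:3][CH2:4][CH3:5])[O:6][CH2:7][CH2:8][NH2:9]
[Br:1][CH2:2][CH2:3][CH3:4].[O-:5][CH:6]([CH3:7])[CH3:8]>[Na+]>[Br-:1].[CH2:2]([CH2:3][CH3:4])[O:5][CH:6]([CH3:7])[CH3:8]
[Br:1][CH3:2].[OH:3][CH2:4][CH2:5][NH2:6].[cH:7]([cH:8]1)[cH:13][cH:12][c:10]([cH:9]1)[CH3:11]>[Na+].[OH-]>[Br-:1].[CH3:2][O:3][CH2:4][CH2:5][NH2:6]
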