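# epmm wavefunction table v1
# SHELL <label> <n> <zeta 1/Bohr> <occupancy> <core|valence>
ELEMENT H
SHELL 1s 1 1.000000 1 valence
ELEMENT C
SHELL 1s 1 5.672700 2 core
SHELL 2s 2 1.608300 2 valence
SHELL 2p 2 1.567900 2 valence
ELEMENT N
SHELL 1s 1 6.665100 2 core
SHELL 2s 2 1.923700 2 valence
SHELL 2p 2 1.917000 3 valence
ELEMENT O
SHELL 1s 1 7.657900 2 core
SHELL 2s 2 2.245800 2 valence
SHELL 2p 2 2.226600 4 valence
ELEMENT P
SHELL 1s 1 14.557800 2 core
SHELL 2s 2 4.510000 2 core
SHELL 2p 2 4.912500 6 core
SHELL 3s 3 1.880600 2 valence
SHELL 3p 3 1.628800 3 valence
ELEMENT S
SHELL 1s 1 15.540900 2 core
SHELL 2s 2 4.880200 2 core
SHELL 2p 2 5.314400 6 core
SHELL 3s 3 2.036400 2 valence
SHELL 3p 3 1.827300 4 valence
ELEMENT MG
SHELL 1s 1 11.608900 2 core
SHELL 2s 2 3.696000 2 core
SHELL 2p 2 3.681000 6 core
SHELL 3s 3 1.102500 2 valence
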