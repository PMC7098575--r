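# Synthetic stand-in for a KEGG BRITE reference hierarchy flat file.
# Category structure: 4 functional categories under 'Genes and Proteins',
# 45 functional hierarchies in total, 9 of them under the metabolism
# category. Hierarchy identifiers and names are synthetic.
A<b>Genes and Proteins</b>
B  Orthologs and modules
C    sy00001  Synthetic functional hierarchy 01
C    sy00002  Synthetic functional hierarchy 02
C    sy00003  Synthetic functional hierarchy 03
C    sy00004  Synthetic functional hierarchy 04
C    sy00005  Synthetic functional hierarchy 05
C    sy00006  Synthetic functional hierarchy 06
C    sy00007  Synthetic functional hierarchy 07
C    sy00008  Synthetic functional hierarchy 08
C    sy00009  Synthetic functional hierarchy 09
C    sy00010  Synthetic functional hierarchy 10
C    sy00011  Synthetic functional hierarchy 11
C    sy00012  Synthetic functional hierarchy 12
C    sy00013  Synthetic functional hierarchy 13
C    sy00014  Synthetic functional hierarchy 14
C    sy00015  Synthetic functional hierarchy 15
B  Protein families: genetic information processing
C    sy00016  Synthetic functional hierarchy 16
C    sy00017  Synthetic functional hierarchy 17
C    sy00018  Synthetic functional hierarchy 18
C    sy00019  Synthetic functional hierarchy 19
C    sy00020  Synthetic functional hierarchy 20
C    sy00021  Synthetic functional hierarchy 21
C    sy00022  Synthetic functional hierarchy 22
C    sy00023  Synthetic functional hierarchy 23
C    sy00024  Synthetic functional hierarchy 24
C    sy00025  Synthetic functional hierarchy 25
C    sy00026  Synthetic functional hierarchy 26
C    sy00027  Synthetic functional hierarchy 27
B  Protein families: metabolism
C    sy00028  Synthetic functional hierarchy 28
C    sy00029  Synthetic functional hierarchy 29
C    sy00030  Synthetic functional hierarchy 30
C    sy00031  Synthetic functional hierarchy 31
C    sy00032  Synthetic functional hierarchy 32
C    sy00033  Synthetic functional hierarchy 33
C    sy00034  Synthetic functional hierarchy 34
C    sy00035  Synthetic functional hierarchy 35
C    sy00036  Synthetic functional hierarchy 36
B  Protein families: signaling and cellular processes
C    sy00037  Synthetic functional hierarchy 37
C    sy00038  Synthetic functional hierarchy 38
C    sy00039  Synthetic functional hierarchy 39
C    sy00040  Synthetic functional hierarchy 40
C    sy00041  Synthetic functional hierarchy 41
C    sy00042  Synthetic functional hierarchy 42
C    sy00043  Synthetic functional hierarchy 43
C    sy00044  Synthetic functional hierarchy 44
C    sy00045  Synthetic functional hierarchy 45
A<b>Compounds and Reactions</b>
B  Synthetic compound category
C    sy90001  Synthetic compound hierarchy
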