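# Default group-level trophic conventions for marine protist groups.
# rank: species | genus | family | group; category: autotroph |
# heterotroph | mixotroph | parasite | NA.  More specific ranks win.
taxon	rank	category
Bacillariophyta	group	autotroph
Mamiellophyceae	group	autotroph
Cryptophyceae	group	mixotroph
Chrysophyceae	group	mixotroph
Dictyochophyceae	group	mixotroph
Trebouxiophyceae	group	mixotroph
Chlorophyceae	group	mixotroph
Rhodophyta	group	mixotroph
Prymnesiophyceae	group	mixotroph
Raphidophyceae	group	mixotroph
Ciliophora	group	heterotroph
MAST	group	heterotroph
Picozoa	group	heterotroph
Bicoecea	group	heterotroph
Cercozoa	group	heterotroph
Telonemia	group	heterotroph
Centroheliozoa	group	heterotroph
Katablepharidophyta	group	heterotroph
Choanoflagellida	group	heterotroph
Syndiniales	group	parasite
Labyrinthulea	group	parasite
Oomycota	group	parasite
Perkinsea	group	parasite
Pirsonia	group	parasite
Apicomplexa	group	parasite
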