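substance_1,substance_2,substance_3,gouter,cosmiques
acetazolamide,zolpidem,,5,2
acetazolamide,hydrochlorothiazide,,2,2
acetazolamide,prednisone,,3,1
acetazolamide,betamethasone,,3,0
acetazolamide,methylprednisone,,0,1
acetazolamide,metoprolol,,1,0
acetazolamide,zopiclone,,0,1
acetazolamide,zolpidem,bisoprolol,0,1
acetazolamide,benzoylecgonine,pseudoephedrine,1,0
acetazolamide,codeine,hydrocodone,1,0
zolpidem,caffeine,,1,0
zolpidem,prednisone,,1,0
zolpidem,THC,,0,1
zolpidem,zaleplon,,0,1
zolpidem,codeine,,0,1
zolpidem,dihydrobupropion,,1,0
prednisone,THC,,0,1
hydrochlorothiazide,prednisone,benzoylecgonine,1,0
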