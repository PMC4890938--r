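label,drug_class,is_class,metabolite_of,gouter_pct,cosmiques_pct,both_pct,both_ci_low,both_ci_high,conc_mean,conc_sd,conc_min,conc_max,n_positive_is_one
diuretics,diuretics,1,,24.9,19.1,22.7,18.5,27.0,,,,,0
acetazolamide,diuretics,0,,22.4,17.6,20.6,16.5,24.7,44630,96857,20,491100,0
hydrochlorothiazide,diuretics,0,,1.9,1.3,1.6,0.4,2.9,1935,3620,4,10048,0
hypnotics,hypnotics,1,,12.7,13.3,12.9,9.5,16.4,,,,,0
zolpidem,hypnotics,0,,8.2,8.7,8.4,5.6,11.2,9,23,0.1,127,0
oxazepam,hypnotics,0,,1.7,1.4,1.6,0.3,2.8,67,85,3,222,0
zopiclone,hypnotics,0,,1.3,1.4,1.3,0.2,2.4,185,313,11,739,0
lorazepam,hypnotics,0,,0.9,0.0,0.5,0.0,1.3,2858,3816,160,5556,0
bromazepam,hypnotics,0,,0.4,0.0,0.3,,,23,,23,23,1
zaleplon,hypnotics,0,,0.0,0.7,0.3,,,3,,3,3,1
brotizolam,hypnotics,0,,0.0,0.7,0.3,,,1,,1,1,1
glucocorticoids,glucocorticoids,1,,3.7,3.3,3.5,1.8,5.3,,,,,0
prednisone,glucocorticoids,0,,2.2,1.3,1.9,0.6,3.2,391,306,11,776,0
prednisolone,glucocorticoids,0,prednisone,1.9,1.3,1.6,0.4,2.9,939,1346,11,3823,0
betamethasone,glucocorticoids,0,,1.1,0.0,0.7,0.0,1.5,25,15,13,42,0
budesonide,glucocorticoids,0,,0.4,0.6,0.5,0.0,1.1,15,6,11,19,0
methylprednisolone,glucocorticoids,0,,0.0,1.3,0.5,0.0,1.1,639,831,51,1226,0
stimulants,stimulants,1,,4.1,1.3,3.1,1.4,4.7,,,,,0
caffeine,stimulants,0,,1.1,0.6,0.9,0.0,1.8,7725,629,7000,8300,0
benzoylecgonine,stimulants,0,,1.1,0.0,0.7,0.0,1.5,253,263,68,439,0
pseudoephedrine,stimulants,0,,0.7,0.0,0.5,0.0,1.1,10940,14228,879,21000,0
ephedrine,stimulants,0,,0.4,0.0,0.2,,,9,,9,9,1
N-ethylnicotinamide,stimulants,0,,0.4,0.0,0.2,,,299,,299,299,1
heptaminol,stimulants,0,,0.0,0.6,0.2,,,127,,127,127,1
dihydrobupropion,stimulants,0,,0.4,0.0,0.2,,,665,,665,665,1
THC,cannabinoids,0,,4.6,2.6,3.8,2.0,5.7,44,44,8,152,0
narcotics,narcotics,1,,2.2,3.3,2.6,1.1,4.1,,,,,0
codeine,narcotics,0,,1.5,2.6,1.9,0.6,3.2,379,490,11,1297,0
morphine,narcotics,0,codeine,1.5,2.6,1.9,0.6,3.2,70,91,6,274,0
methadone,narcotics,0,,0.4,0.0,0.2,,,5,,5,5,1
hydrocodone,narcotics,0,,0.4,0.0,0.2,,,480,,480,480,1
tramadol,narcotics,0,,0.0,0.6,0.2,,,358,,358,358,1
beta-blockers,beta-blockers,1,,1.5,0.6,1.2,0.1,2.2,,,,,0
betaxolol,beta-blockers,0,,0.7,0.0,0.5,0.0,1.1,201,16,190,212,0
metoprolol,beta-blockers,0,,0.7,0.0,0.5,0.0,1.1,44,14,34,54,0
metoprolol acid,beta-blockers,0,metoprolol,0.7,0.0,0.5,0.0,1.1,109,129,17,200,0
bisoprolol,beta-blockers,0,,0.0,0.6,0.2,,,64,,64,64,1
metabolic modulators,metabolic modulators,1,,0.7,0.0,0.5,0.0,1.1,,,,,0
methoxytamoxifen,metabolic modulators,0,,0.4,0.0,0.2,,,25,,25,25,1
anastrozole,metabolic modulators,0,,0.4,0.0,0.2,,,250,,250,250,1
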