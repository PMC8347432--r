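proton,conc_mM,shift_ppm
H5,0.002999999999999999,5.449848905516673
H5,0.005172162522051537,5.450162867382061
H5,0.008917088384838174,5.444265477284661
H5,0.015373543449960348,5.444243052908852
H5,0.026504821754338617,5.441020026717266
H5,0.04569574857714884,5.434359266650112
H5,0.07878194606927301,5.425048061727078
H5,0.13582434295792645,5.409715808759312
H5,0.23416852540975397,5.390944712468795
H5,0.4037192236561343,5.3684203163732604
H5,0.6960338126753335,5.344702513040476
H5,1.2,5.321676561063696
H11,0.002999999999999999,7.616729871155738
H11,0.005172162522051537,7.6185181844107035
H11,0.008917088384838174,7.620456365186213
H11,0.015373543449960348,7.61307760628575
H11,0.026504821754338617,7.605038895274626
H11,0.04569574857714884,7.599963951720278
H11,0.07878194606927301,7.587564861440437
H11,0.13582434295792645,7.566676478651532
H11,0.23416852540975397,7.544025900359366
H11,0.4037192236561343,7.517956358933753
H11,0.6960338126753335,7.486796627403126
H11,1.2,7.459756781424998
H12,0.002999999999999999,7.977089669991264
H12,0.005172162522051537,7.980202480201798
H12,0.008917088384838174,7.974119648703682
H12,0.015373543449960348,7.965444059571426
H12,0.026504821754338617,7.963272413038673
H12,0.04569574857714884,7.954843176277855
H12,0.07878194606927301,7.936767349403421
H12,0.13582434295792645,7.911249617601651
H12,0.23416852540975397,7.888319890296772
H12,0.4037192236561343,7.853028617322645
H12,0.6960338126753335,7.814917428122029
H12,1.2,7.778368117503961
H14,0.002999999999999999,7.3452852279033465
H14,0.005172162522051537,7.350011524846383
H14,0.008917088384838174,7.3468676038930445
H14,0.015373543449960348,7.340253367549401
H14,0.026504821754338617,7.333979218489014
H14,0.04569574857714884,7.32674464049591
H14,0.07878194606927301,7.310747564544582
H14,0.13582434295792645,7.289312215699553
H14,0.23416852540975397,7.269600719225022
H14,0.4037192236561343,7.236040933418541
H14,0.6960338126753335,7.205605941284955
H14,1.2,7.172786449310489
H19,0.002999999999999999,1.378031132330072
H19,0.005172162522051537,1.3815016897067638
H19,0.008917088384838174,1.3763677568702173
H19,0.015373543449960348,1.3747889673487252
H19,0.026504821754338617,1.3766241606995955
H19,0.04569574857714884,1.3694713564937266
H19,0.07878194606927301,1.3668796838591317
H19,0.13582434295792645,1.3622128759702148
H19,0.23416852540975397,1.3483838018733154
H19,0.4037192236561343,1.3412932785614258
H19,0.6960338126753335,1.3326614861795862
H19,1.2,1.31925618529069
H23,0.002999999999999999,8.099549052808584
H23,0.005172162522051537,8.10147704509302
H23,0.008917088384838174,8.094354334405159
H23,0.015373543449960348,8.102337385455353
H23,0.026504821754338617,8.101649862608422
H23,0.04569574857714884,8.108430076016548
H23,0.07878194606927301,8.103587409649199
H23,0.13582434295792645,8.109791203682992
H23,0.23416852540975397,8.114714408412906
H23,0.4037192236561343,8.121012619516412
H23,0.6960338126753335,8.125023553091218
H23,1.2,8.131359973933305
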