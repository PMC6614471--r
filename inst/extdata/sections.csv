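section,type,tiles_y,tiles_x,ftir_spectra,la_rows,la_cols,la_spectra
1,fibroadenoma,31,47,5967872,110,119,13090
2,fibrocystic,45,35,6451200,160,118,18880
3,ductal hyperplasia,39,34,5431296,163,160,26080
4,fibroadenoma,26,35,3727360,113,159,17967
5,ductal hyperplasia,38,20,3112960,256,215,55040
6,intraductal papilloma,36,40,5898240,157,148,23236
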