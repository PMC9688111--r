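>AMOT_77 species=Homo_sapiens site=77
RQEPQGQE
>Arpin_213 species=Homo_sapiens site=213
REQGDGAE
>ATG9A_233 species=Homo_sapiens site=233
RLPGLGEA
>Axin1_22 species=Homo_sapiens site=22
RPPVPGEE
>CASC3_146 species=Homo_sapiens site=146
RQSGDGQE
>Dicer1_656 species=Homo_sapiens site=656
RELPDGTF
>GMD_12 species=Homo_sapiens site=12
RGSGDGEM
>Golgin45_18 species=Homo_sapiens site=18
RGAGDGME
>IRAP_96 species=Homo_sapiens site=96
RQSPDGAC
>Mcl1_78 species=Homo_sapiens site=78
RPPPIGAE
>MERIT40_28 species=Homo_sapiens site=28
RSNPEGAE
>MERIT40_48 species=Homo_sapiens site=48
RSEGEGEA
>NKD2_16 species=Homo_sapiens site=16
RESPEGDS
>Notch2_1726 species=Homo_sapiens site=1726
RREPVGQD
>NuMA_1743 species=Homo_sapiens site=1743
RTQPDGTS
>PEX14_310 species=Homo_sapiens site=310
RMEVQGEE
>PEX14_350 species=Homo_sapiens site=350
RRGGDGQI
>SH3BP2_415 species=Homo_sapiens site=415
RSPPDGQS
>SH3BP5_269 species=Homo_sapiens site=269
RGCGVGAE
>SH3BP5_368 species=Homo_sapiens site=368
RSECSGAS
>SOX9_257 species=Homo_sapiens site=257
RPLPEGGR
>SOX9_271 species=Homo_sapiens site=271
RDVDIGEL
>Striatin_302 species=Homo_sapiens site=302
RSAGDGTD
>TAB182_1508 species=Homo_sapiens site=1508
RPQPDGEA
>TRF1_13 species=Homo_sapiens site=13
RGCADGRD
>USP25_1049 species=Homo_sapiens site=1049
RTPADGR
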