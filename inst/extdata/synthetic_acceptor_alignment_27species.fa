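>reference_taxon
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_02
GCTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_03
GGTCCTTTTTCTCTTTACAGCAC
>synthetic_taxon_04
GGTGCTTTTTCTCTTTACAGCAC
>synthetic_taxon_05
GTGTCTTTTTCTCTTTACAGCAA
>synthetic_taxon_06
GGAACTTTTTCTCTTTACAGCAC
>synthetic_taxon_07
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_08
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_09
GGTGCTTTTTCTCTTTACAGCAA
>synthetic_taxon_10
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_11
GATTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_12
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_13
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_14
GGTCCTTTTTATCTTTACAGCAC
>synthetic_taxon_15
GGATCTTTTTCTCTTTACAGCAC
>synthetic_taxon_16
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_17
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_18
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_19
GGATCTTTTTCTCTTTACAGCAC
>synthetic_taxon_20
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_21
GGGCCTTTTTCTCTTTACAGCAC
>synthetic_taxon_22
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_23
GGTTCTTTTTCTCTTTACAGCAG
>synthetic_taxon_24
GGTTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_25
GGTTCTTTTTCTCTTTACAGCAG
>synthetic_taxon_26
GCGTCTTTTTCTCTTTACAGCAC
>synthetic_taxon_27
GGTTCTTTTTCTCTTTACAGCAG
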