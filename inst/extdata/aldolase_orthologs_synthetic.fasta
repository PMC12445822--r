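>Hs
IKDRFGPHQNWDDYLPVFIKRAERYTCIIRLHESNYEVKYLLTHIFCYTCCLRDLTRNRPVVQAVDKGWYFYPVVGKFRA
RTTAKAHLSKQYDEFVIFKKSKIWDHCKTASKPWWAWMHQISCNFVNMRCQIFGNMMYMRYGYGWSKQKLSLQACFNTMW
ARWPGAGYKPRAMDYATVYRYTMFHKFCQEEKHGYLRWELPPGFACWFTMIVNMKQHNAKGMMLLEYSTVFHFNEQGIVL
FWFEKMGERGFMFVIQATCFERPGLWKRVDKQAHAMYPHCECIKCGPRDGIARWHMIYHCGFPEFPTQHEKVREADICPR
NHQNKVKDERTTFECSMDKKRYHKTYVEQRWEMSMPWQEK
>At
CNQKPLEQVEVGFFLTMCWRVWGGQVMKPGHNPMNRNLIKDPFGPHQNWDDYLPVFIKRAERYTCIIRLHESNYEVKYLL
VHIFCYTCCLRELTRNRPVVEAVDKGWYFYPVVGKFRARTTAKAHLSKQYDEFVIFKKSKIWDHCKTASKPWWAWMHQIP
CMLVNQRCQIEGNMMYMRYGYGWSKQKLSLQACFNTMWAREKGAGYKPRAMDYVTVYEYTMFHKFCQEEKHGYLRWMLPP
VFACWFTMWVNMKQGNAKGMMKLEYSTVFHFNEQGIVLFWFEKMGERGFMFLIQATCFERPGCWKRVDRQAHAMYCHCEC
IKCCPHDGIARWHMKYHCGFPEFPTQREKVREADICPRNHKNKVKDERTTFECSMAKDRYHHTYVEQRGEMSMPWMVK
>Dr
TYSRPGPHQNWDDYLPVFIKRAKRYTCIHRLHESNYEVKYLLTHIFCYTCCLRDLTRNRPVVQAVDKGWHFYPGVGKFRG
RTTAKAHLSKQYDTFVIFSKSTIWDHCRTASKPWWAWMHQISCNFVTMRCQIFGNMPYMRYGYGWSKQKLSLQACFNTMW
ARWIGAGYKPRAMDYATVYRYTMFHKFCQEEKHGYLRWELPPGFACWFTMIVNMKQHNWKGMMCLEYSTVFHFNEQGIVL
FWFEKMGHRGFMFVCQATCFERPGLWKRVDKQAHAMYPHYDCIKCTPRDGIAMWHMIYHCGFPEFPTQHEKVREADICPR
NHQNYVKHERTTFECSMDKKRYHKLYVEQKWEMSMPWQEK
>Ts
CQREHYRLYQRCKCDIKDRFGPHQNWDDYLPMFIKRAERYTCIIRLHESNYTVKYLLTHIWCYYCCLRDLTRNRVVVQAV
DKGFYFYPVCGKDIARTTAKAHLSKQYDEFVIFKKSKIWDHCMTPSKPWWAWMHQISCNFVNMRCQCFGNMMYDQYGYGW
SKQKLSLQAIFNTMWARWPGAGYKPRAMDYYTVYRYTMFHKFCQEEKHGYLRWELPPGFACWFTMIVNMKDHNLFYMMLL
MYSTVFHFNDQGIFQFFFEKMGERGFMFVIEATCFERPGLWKRVDKQAHRMYPHCECHSPGPCDGIRRWHMIYHCNFFEF
PTQHEYVREADICPRNHQVKVIDTRQTFENSMCKKRYPKTYVEQRWEMSMPWQLK
>Dm
RKDRFGPHQNWDDYLPVGSKRADRYTCIIRLHESNYEVKYLLTHIFCYTCCLRDVTRTRPVVKAVDKGWYFYPVVGKFRA
RTTASAHLSKQYDIFVIFKKSKIWDYCKTASKPWWEWMHQISCNFDNMRCQIFGNMMYMRYAYGWSKQKLSLQACFNTMW
MRWPWAGYKHRAMDYATVYRYTMFHKQCQEEKHGYLRWELKPGFACWFTMIVNMKQHNWKGMMLLEYSTVFHFNEQGIVL
FWFDKMNEPGFMFWIQACCFERPGLWKRVYKQAHSMYPSCECILCGPRDGIARWHMIYHCGFPEFPTQIEKVREADICPR
NHQNMVKDERTTFECSMPTYRYHKTYVEQGWEMSMPWQEK
>Tc
IYIQWVYAWHIKDRFGPHQNWWEYLPCFIKRAERYTCIIRLHESNMEPNYLLTHIFCYTCNLCDLTRNRPVAKNVDKGWY
YYPVVGKFNLRTTAKAQLPEQYDEFVIFKKSKIWAHCKTASKPWWRAMHQISCNWVNMRQPIAYARMYMRYGYGWSKQKL
SDQACFNTMYARWPGACYKPRAMNYATVYRYTMFHKFCQEEKHGYLRSEHWPGFACVFTMIPLMWQHNAKGKMLLEYSTV
FHFNEQGIVLFWFEKMGERPFMFVIQATCMEIPGLEGRVDKQAHAMYPTCECIKCGPRDGMARWHMIYHDGKEEFPTYHE
KVYEADDRPRLFQNKVKDERTTFECSMTKKRMRKTYHEQRWEMSMHEQEV
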