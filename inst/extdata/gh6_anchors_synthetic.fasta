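>Tfu_0620_like|exo
YSKTFRMDNPSLMAYMDREVTIDCSFGHTMWRCVIKMEEWYSPAGVERLEYSRSRPQCGW
SENNAIMLWPCEAMAFPHGVNIEHTHLWDAPWTIMDPGCYRVDKIFPMCGVTGHWHYTEV
QWNCHGPRQRIDMQFAVRYNKQGDSYDMNVPAFGTIYQTAVFNLYRGGMRLACWFSMEAN
HWKADEWIWDHAGMWNGMTIGQDPVQVFHGYCSHGKQVYHGQTSAQDAMLYLQPDNQYDQ
ACYMSHRDVFSHYHEPWYWCDWHMAGPNVTVCWEDGFKNDWNTWGWEHAVWLQTFEEFEW
>XCC3160_like|exo
YWKTGRADNPSLIWEMDREVTDDRSFGPTMWQCTYQMTEWYSGAGCEALEYSRERQAFGN
SMNAATMDYPCEAKIGPGDVNIMHTHLWIAPVHILWPMCYRGDKCFWMSGWSGHWWYTGC
QWACHMPRGRIDMQFATVYNWPSDSYDMNVPAFRTIYPTAVFNGYRTGMSEACAFLPWMN
HWKADEVIEDALDWWNGMTEGQDPVPVANGYCDFTKQVYMGQTSAQDAWSYLQPDQQYDQ
AYYMQHRDERSHYHMAWQWNMWHMANPNPWVCGFDGFKNDWNTWKWEHNVWLTPGEEFEW
>XCC3534_like|exo
YWKTRKMDNPSLHVPMDRNVTIDCSFGPTMLRCVCQKIVWYSTAHCEALEISRSRQQFGN
SMNAFWMLWPCEPPAGPEQVNIEHTHLWYAPWHLMTPGCYRGDNIFEMCGWSGHWSMTEC
SWCCHGPRGRIDMQFADRYLKPSDSYDVKVPAFMTICPTAVFNGDRGGMYLACAFSRCKV
DWKWDSVIWNAYGWWNFFTYGQDPRPVQHGYCSHIKQWYAGQTSAQYAMSSLQPDIKYDP
AYYMSHYDVVSHYHEAWQWNDWHMINPNKWVCWFDGFKNDWNTWPDEHNVWLQTFNWFEW
>KNP414_06149_like|exo
YWKTWRMDNDSLMWPWDKEVTIYCSFWCTEYRCVCQMTEWYSPVPCEALEYARSPEQFGN
SMNACIMLWPSEAMAGPKLVNIEHTHLWITPWHIFTKGCYRGDKITPMCGAGGHWWYTEL
QWACHGPRGQIDMQFAVRYMKYDDSYDMNVPAWMTIYPTAVFNSVRGWMRLACAFSPCMN
HWKADEVIWDGHGWWWVMTPWQGPVPMAHGYCSHHKWVYMGQTSTQDAMSTLQPDNQYDQ
LYYMSHRDVWSHYHYAWQWNDWHMANPNKWVCFFDGFKNDWNTWPWEHNKPLQTFSWFEW
>RSp0583_like|exo
YWKTQRRDNPSLMLEMNREVTIDCWFGNTKGRCVCQWPEWYSPARCEALEYSRSRQQFGN
SMNAAIVLWPCEARAGPHMVNIEHTHLRIAPKNIMTPGLYRGDKFFPMCGWSGTWWYTEM
FWACHGPRGRIWMQFAVRYNKPSDSYDMNVQFFDTIYPRADFNGYVGGMRLACAESPCMN
HWKADEVIWDHWGWWNGMTEGPDPVPVAHGYCSHHKQVYMGQLSAQDAMYYLQPSFQYDF
AYYSSHRDVVSHYHEAWQQNRWHMANCNKWVCWIDGFKLDWNTWPWEHNVWLDTFEAFEW
>cbhII_Pchrysosporium_like|exo
YWKTRRTDNPFLMWPMDREVTIDCLFGYTMWRCVCQMTEWYSPHGCEALEYSRFRLQISN
SMNAGIMLWPPEAMAGPHLQNIEHTHLLVASWHTMTPRCYRGDKIFIMCGWSGHWWVTEC
QWACHGPRGRINMQFAVHHNKPSPSYKLHKPAFMTIYPTMFFNGYYGGMRPACAFSGCMN
HWKADEVIFDAYGWWSGMTEGQLPVPVSLGMCSHHKQVYMGQPSAQDAMSYLQPDNQYRQ
AYYMDHRKVVSHYHEAWWWNDWHMAQWNKWVCWFYGMLNDWNTWMWEHDVWLQSFTWFSP
>Tfu_1074_like|endo
MLFPFDDDYKMLDVASFWNLTLMRGFMKGRMVKQGCEGMVKTMMDESQIMLVQIFAVMTH
AKISGTMVCIWYQLCLLKADPLDAGSYPLKMCQKHPFVSFASYFWRACDRHYMQLRAAHG
PTKYFMWGRAMAFAGFYSSRAREMRAHDWDSSTEVHSRFGEYHIHVYKQNWNWAWDMFRV
GAYPLQGDVAISSWMMQYITHMQMMEPCWMPGCRLIIKQDLNAKQDTVLPRAEVLNMRKV
HMDYFRQVFSELPKFWHKEEEEGATNAQGSEKGFIPCIMEYSNQEDMCMFNKNQPAYRCY
>Cfla_2912_like|endo
GRFPFGDDYKMNDVCLNYIETLNIGWPKQRMMKQGCTGMGQTYMDESYIMLVQNFLVRTH
VLIKTTMICRWYQLCLHAADLGDAMSEPLPMCQKRPFVSFESHFNRFCDFHYMQLWATRE
PNPYFMTGMSMAFQKFYSRRANEMRAHDHDSSTEVHRRFGEYHNHGFKQIATWTIDMFCV
GAYTLEFDHRISSAMMQYRTHMAMMEPCRMPGCRSINMEDLNAKQYTVLPRAEVWMDRIV
MMDPNRNVHEELDIFWCKGEEEDPTNMQGSWKDHIPAIMECSNVEDTCMFNHNQGAYRPA
>CenA_Cfimi_like|endo
SEFPFGDDYKCNDVCLFYIETLMIEFMKGRMVKKGQTWMGQTYMDENQEALVQIFAAMTH
FKIKGTMVCIWKQLCHHAADPGDAGKEPLNMCQKHHFWSFAGYFNRFYDFHYMGLHAAHG
PTHYFMAPMSSAFAGFYSSRANEYPAHDQDSSTEVHSRFGWYHIHVYKQIWNWHWDMHMV
GAFTTQLDHMIHEGMMVYITYMAMMEPCRMYGCRLNNEEDLSAAQNTFLPCAGVWMMRIV
HMDGNCQVFVELDIFWHKQEEEQDTNAQGSDKAEDPCTMEDSNVEDWCMMNENQPAYRPY
>Jden_0538_like|endo
YLFPFGDDYKMNDVCLFLIETLMIGFMKGRMVKQGCTGMGDTYMDESWIPLVQIFAVMTH
AKIKGTMVCRWYQLCLHAADPNDAGSYPLNMCQKHPFVSFASYFNMFCDFHYMQLWAAHG
PTPLFMWGWSMAFAGFYSSRANEYRAHDQDSSTEVHHRFGGYHIHVYGQIWNWHWDFFMV
QAYTLQFFHMISSAMMQYRTGMAMMEPCRYPICRLINMESQNAKQLTVLPRAEVWMMRIV
HMDYNRQVFVILYIFWHKHEECADTNAQGSEKRETPCIMEDSNVEDTCMFNNNQPAYMIS
>Snas_6330_like|endo
SLFFFGDDYKMNDVLLFYAPTLMIGFMKGRMVLQSCHPMGQTTMDESQIMDVQWFNVHGH
ACIKGTMICRWYQLRLHALDPGDAWSEPLNMCQAHPFVSFHFYFNEFCDNHYMNLWAATI
PTLYFPWGMSMAFAYFYDSRANMRRDHNQNSSTEKGSRFGEYHIHVYKQEINWHWDMFMV
YAYTLAFDHMISKAMMQQRTYMFMMYPCRSPGRRLINMEDLNAKQNRVLPRAEVHMMDIV
EMDKNRQVFCELWIFWHFGEEEDDTNTQGTEKRQIPCSMADHNVPDTCIFNNPQPGYRPY
>Acel_0135_like|endo
WLFPFGHDYKMNDVCLFYIETLMIGLPLGLMVKQGCTGMGQTYHDESQPLLVQPFGMETH
AKIKGTVECRWYQLCKHAADPMDAGSEPLNMLQKHPQLSFASYFNWPCDFHTMQLWCAHG
RTPYFMTTMTMAMAGFISSRAMEMRAHDQDSVMEVHSRLGEWHIHMYWQIWNWHSNMFMW
GAYMLQFDEMGSYDMMQYRTYDAMLEPCRYPGCRLINMEDLNAKQNTVLPRAEVWSMDIV
KMDYNRQVFVELDIFWHKQEEEDDRTAQGSEKREIPCRCEDSNVEDTVMFNWARIAQRPL
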