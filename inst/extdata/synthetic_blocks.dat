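ID   SYN0001; BLOCK
AC   SYN0001; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) HFKMPYSLWDSQLRIICKQRIIHNTLPLKPNFWRDPMWRPPTRGDPDQRNDHSNTDMYYG  1.00
s02      (    1) HSQESYLLGISQVNIRCKQRQWHNTNMLAPWCWTYFMLRPPIRHSISLINCYSPTDMYYF  1.00
s03      (    1) HQYEFGELWISCFNIWCKQTITHNTNGLIPQFWRGMERRPWQRGDYSQHQDHSDTYMYYG  1.00
s04      (    1) NKQQFYELWIQQVGIICIQRITHTTNFLPPWFWRYQMWRPPTRGDPSQHNDDSPTHMYYG  1.00
s05      (    1) RPGGMSCCDNAPPHPCPPWVIGWCDISTDMWASPKTWEYATHSIRVCGPNRWGRARYAKF  1.00
s06      (    1) RFGGKSVIQRAPTHGGCVWVIGQVDINTKMDISGVVIEQASVAIQQYWQNRYGRAGYAKF  1.00
s07      (    1) RPGGKSVMQRTPTHPGCEWVNCQVEIVTKMWASGVVLEQKTIAIRMHWQNRYKRARYIKL  1.00
s08      (    1) RCCGKSVMTRAPTHTECPSVHGKQDIITKMWASGWLEEQFTAEIRVCWQNHLAMMTYMKF  1.00
//
ID   SYN0002; BLOCK
AC   SYN0002; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) SCRCQQSVEALYQDDTFFTYPHKMRHHMIVPGMMAGKFYLFNTKDGGACDLNRPSNYAII  1.00
s02      (    1) SCRCCGSVELSIQDYTFFKIVQDMPHHMPDVGDGAHRFELFGGKDGHNNTSNFITNYTIH  1.00
s03      (    1) RCRIAQSVRECYRSKPFFYCVQKYPHHMIWVINMHGRINLFMGKNFKSNDHNRPTMYAIW  1.00
s04      (    1) SCTCCQSVELSYQDDTIFPCKSAMPHHHIWLGDMQGTFNLFRGKDFKSWDHNRPTNYNDA  1.00
s05      (    1) YNNRFWVNLLGCNCQETRFVRGPQYKPIYMWIFQDAPTMEPFFAQLPSQQRRNYWLFFGW  1.00
s06      (    1) KNNRFCVNLMHCNCTNTTFAVGTQYKPIYMWIFQNADTMHPFFAKKHDVAKENPWIFFPW  1.00
s07      (    1) TAWRLWQNLLGCNCQNTTPVVGPQYKDAGMWWWQNNPTMSPFFAHLTVQQRENPALRFMW  1.00
s08      (    1) YNERGWVNLLGKNCQNTTHVVGPQLKPIYPWIFVNAPTMHPFFKQLFDQQADNNWLFFMF  1.00
//
ID   SYN0003; BLOCK
AC   SYN0003; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) ETILRAGSPDGCQTKHSLEHIQPWRLTFHTCTVPEHTAFFVGRHEHRCAHLGYSIMLNRE  1.00
s02      (    1) ETINRAGSPFICQIRRSLEFRQPERTRPVDKSVPELTAFFVDRHESRKAHLVPSPKSNWE  1.00
s03      (    1) EHILVAGSPDGYVMSRMLEFSQKERISFHTCSVPELTAFFVDDHEHSDAHKWYSPMSNWE  1.00
s04      (    1) RTITRAGSPDTCQMPHSAYFQCPERTGFHTCSRNCTTAFFVDRHEHLDAHLVYDPWSNWI  1.00
s05      (    1) LKQWHILDYPLAGEIWHVFFTWHRGMRPPYWDTGVISPMWQYIPGAKAVIQECCPCPEIT  1.00
s06      (    1) SLQWGLLDYPGMGHIWHVAKTRCRNDHTLNMDDSVHTPMGQWIREAPAVTMALQGCPEIG  1.00
s07      (    1) SLQWRLLDYCLSSEIEYVFPTWARWFYMIRWDCSVHHPMGQAIRGAKVITMANCPGPSVI  1.00
s08      (    1) SFQWNGADWCRSGEGWHVFTTVSPHMYDTYWCWSVHSPDGQAIREAKAKQMAMWPWPEIG  1.00
//
ID   SYN0004; BLOCK
AC   SYN0004; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) MNLPMHGGRSTYNQCECPFIDEEKGEHWNLVQFIMCSDETNEKPYARWSKARFVSCHKSH  1.00
s02      (    1) TNLDMMCGRMHQYCCVCPGAAHSAGEHWCLVQWGMQSDEINIDPYNRHSRAQWISAHYSH  1.00
s03      (    1) WNWDMHEGRSPYYQCVCHFWWVCWGEHWCLVQPGMRHDETGEKPKNRWMRAAMVSAHCAH  1.00
s04      (    1) ITLYYHHGRSHYYQCVCPFAAESWGEHWHLVQLGIRSDARNEKPMNRWSRLEAVLAHKSH  1.00
s05      (    1) MTWKDKCIESAWAGGRYRKWAHNHRQPSYYVIVRFCAWTSNHQRHRYRYESFMMCYMPQQ  1.00
s06      (    1) MIWKDHNIFSYQICGETRKYAMCHYQESVYCFVRHQAWTNYSWRFMFPYSTKDMIYMWKY  1.00
s07      (    1) GTWKDEKIESHQAGHRTRKAARNYCQESYYSFGRALAWTPNSHSYRFVYEMKMMIYMWKN  1.00
s08      (    1) STWNDHRIEPGPAGGETRESWGQHKYYAYFVFVFRLAWHEDSFDYHRVYATKTVIDMWKQ  1.00
//
ID   SYN0005; BLOCK
AC   SYN0005; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) SPGCLADKQIAYDEDFAVHFIWADSSIERGPDFCNVQKQISSILDQDAWNQCKQIAMLMF  1.00
s02      (    1) SPQCLQDDQDACDTATQVIKIWRNNTFNRGEDFCNVHMQEYSALDSDAWNDQHMDAQQDF  1.00
s03      (    1) QPGCLAMKQHVWYEDFEVICIDHDSTFERGAMFCNVLDQKPMALDDDIWNHQLQSAGWDF  1.00
s04      (    1) SQSCLADKQDADPEDFEVIYIWMDCTAERGADFCNVQMKIPSPLDSDDWNATHSSAMDDF  1.00
s05      (    1) SDWVFDQIYITYSGEKACALDHIWIHLNTAEVYESHFWYVPFRAYYMTMCIYHHIVHLCC  1.00
s06      (    1) IDWVKDWCVIQYSKEKACVLDPIWFYLSTAEPSEVVRWYVPWRAYYTKNQLYHMIVNLCG  1.00
s07      (    1) LDIVKDQLVFRFYGWIKCAKDHIHAALMTAVPSEHAFEYVPFWAYYGYMQYCHHIVHLCD  1.00
s08      (    1) LDWVKWNCVITYVGEKACALHNIWFCLMTACPSEVCFWYPDFRAQYMKMQYYHIISHLAG  1.00
//
ID   SYN0006; BLOCK
AC   SYN0006; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) THGLNMKEFFVVCYFMDDWAQECFHFWFTWFWLMNGAQLGVSNPEMFGHIRHGTDGNGGY  1.00
s02      (    1) CVGLNTKGFHQVCYFWEDTAYWHFRNYRCWGTPPNTAQCKKSRPMMDNMRRWGTDGNIGY  1.00
s03      (    1) CRGLNTKKFMVVYYFMDATAIWCFNLFDCWFMPYNGAQLGDECPYMFGMYRPGTDGWGGM  1.00
s04      (    1) GRGPETKGHWVMEKIMDDTYPWCFRLWFCGAMPPNGALLGKSAPYVFGMARCGTDGNGGH  1.00
s05      (    1) GWFDQRVTLPDAEIKFFYHAPLTIMPTETSYVRLANRTPQSEESENVGGNVHRPCVKHIL  1.00
s06      (    1) WQTEQRVTQADSTVKFESHKPRHIMPPETTYVHLANECPSSDEPWNVGGPVHLWCGKHIH  1.00
s07      (    1) WQWDWSQLFATSNVEFELHWPITIMPTETSYVRLANHPIVWFECWNVGGNVDLWMLKAIH  1.00
s08      (    1) WYTDQRETFAMSRVKFECQDPRTAMGTYYSGVRLANPCPQSDEGWVTGGNYHLYCVKHDH  1.00
//
ID   SYN0007; BLOCK
AC   SYN0007; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) DKPHQQAYTECLTGRDYCDHQEPMGFLFPMMDWSIPTQQYQAHVPILVHAYWFIQMILIM  1.00
s02      (    1) DSQHEQKCRECDNGRGYCVTRGRKSFQFMRMYDYSPMRQVRAHVYGQKHAEWFSAMNLIM  1.00
s03      (    1) AYPFPQTSVRCIKGRGECTHQRRMSFQYRRLVWSIPMQQYSDHVWHLVHVYIFIQMVLIY  1.00
s04      (    1) DSPHQQKYDEWLNTRGYPTHQRRMDFQKKRMYGSIFKQQYSALVWGLEHAYWLIQMVFIM  1.00
s05      (    1) KRQCMDTWSTHVAPLFYGSHHLDLKQEGYMASWGTHDMSIMVMSHASLRWLPWMKCKEMA  1.00
s06      (    1) KYQPMDTPSTHVAPLDLILNSLKLKTELDMPSWGTRDMSIESGSHTELQRGAKMKVKEMW  1.00
s07      (    1) KYQPMDCPFTHEAPLPLILHSLWLKTEGDMHSSYKRDMQIEHDCHFSLQELAWMFFNEMA  1.00
s08      (    1) KYQPTDTPSTHVAHLDGILHSMELKKEWDMGSWGTTDMSIEGDPHAQLQEYAHRKVKEMA  1.00
//
ID   SYN0008; BLOCK
AC   SYN0008; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) TMTGNAWPYNGFTDLSDKDDFCGPFKMYCEAGGMPLGFLHPHLIVNGNHDWFMPRCMGCF  1.00
s02      (    1) THPRLAWCWNWHGIQVDKWLFCAPWKIEREAGGEFLFVLGPFFIVECKSSQFCWRFAGWG  1.00
s03      (    1) THVGLAWCWNSHGTLLDINDPWAIWKMPCEIGGEPLGVGGPFLIVNTKHSWFCWRFNGHG  1.00
s04      (    1) RHPPNAWVWNSHGILHLAEDYCAPWKMDCTAGAEFLPYLPRFLTKNGKTSWTCWRFVGRV  1.00
s05      (    1) STGIDNNSMFAYERGCGHRDNGAKIITGLGDRYDAIFHEEARWQMVPGKGCWCAAEDPET  1.00
s06      (    1) NLGISNISPEAYRRKQHSRKVHAKIITELGDAIDAIFEEEAQWQEGPGKNCWGAFCNPTP  1.00
s07      (    1) STGGSENSPKAYERGSFCRQGGAWICKGLGDKQDAIFHEEAQNQGEPGRTCWQPFCDPVP  1.00
s08      (    1) STGISNNAPRAPENGSVCRDNGAFIHTGCGDKQDPLFHEMAWWQNQPGKGCWQTFCDLED  1.00
//
ID   SYN0009; BLOCK
AC   SYN0009; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) VHTMHKPSLHHSCRCCCLIWYSYDPREHGKQICAHWHWEDNHWHHIQPQEVPHNKSVDNM  1.00
s02      (    1) VHMMHDTAMLYQCCCCHKIGNPVDPFEIGVPGKAHWHGNLNQWCHIVPQHSPYWNSLDHM  1.00
s03      (    1) VHTMHKTCVHWCCRRCNSIGNPVDPQEIKVFGVAHWHTEYNPWHHGVPQMYPYYKSNDKM  1.00
s04      (    1) VHTMADYSGHWCFNKERKIGNPVDPQEIGVQGQQQMSWPYNPAHHIVPTEVPYNKDNDKM  1.00
s05      (    1) PGQTLHIVEGKYMPPVKTGMSHVLIWNCAQDDKRHFEWINYFVQCGHDHSKVGYWKEGWH  1.00
s06      (    1) PGCTGHGVAMKYNCPFWRGGSHRRIWVCASGDKGHATMINDFVVCVYLGSKVEYYEEGIV  1.00
s07      (    1) PECDCWIVAMDAMNDMKECMSHRRIIVCAKDDKRHATWKNDFVQPVYDMSKVEYDEFGFH  1.00
s08      (    1) PGCTGGIVAMKYMYPMATQMSHRVIWACAQDDLNKFTWINDMVRNSSDISTVRCLPEGFV  1.00
//
ID   SYN0010; BLOCK
AC   SYN0010; distance from previous block=(0,0)
DE   
BL   adapted; width=60; seqs=8
s01      (    1) AYDGFKDKQPGCLKELAHCSLCMLPFKEPKKTPFYPLFYGEGAETMACKVNQLLYHTAYP  1.00
s02      (    1) AYQWFAAKPPRFHKELYMNSSRRLPIKLGKKHPFYPQRPEVGANTGWGKTAQITYHTKYP  1.00
s03      (    1) ANTIFAAVQPGAHKFLYMCSSCWLLFKLGMGTIDFGQFPQEGLETKHPKTANITYWKYEP  1.00
s04      (    1) FYCMGAAPVPGAHKYLYMCSSECLLFKLYKKTPDYPQFTQEGAETKRSKIAQCTYHTACP  1.00
s05      (    1) MYLLWKFKLLSAMKRHCYEWLGWNFYFQPHSIWHDYVYMKETPAEHMVVFNAHIWYVNDY  1.00
s06      (    1) MYCNWKFGLLDFMQKLCVQIGGFNDYFQMHNISHDYVIHCRRPVEPMVVHNATIWFVNKT  1.00
s07      (    1) MYNLMCMTLLYFMKRWCYQHCGRANGFPMHNIWHDYVNCKERRIMCMKCSLAHIQYVNFR  1.00
s08      (    1) MKLLWYFMSLAFMDRLCYQWLEFNFQEQMHILWHDYVICKERPHECGVVFNALKWYVNFY  1.00
//
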