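>marker01 synthetic single-copy marker
EIIRTILIYLQFYTTSATQVAHGMSWNMEHHKVHSKIQSYWMWVELQEKMTHCWLNNGLE
GKKADDEQMKCENRYHWHWDTWGEPPCHESNYWPPISNSWGFAQNTVMDHCMQPMNENRQ
EMGWSLPDRNVLLVRKTTWIDSNYVCSKVWQSKDIMWLFAHIAKKCMSCVCWHIEQRSNW
NWYSPRVYH
>marker02 synthetic single-copy marker
MHRLNNLWEQYKFSAGWELHETVFWAFVYQYWWELQLGHYIYKCTVYTPFVCNMGIMGDW
LHKTFRRCHYSYRLYRVRWRVKIVFYSYFMNAFDITRMYKCDMNCHPYKRVRMHEKATKV
ISLDGTMSSEVLIYVPKFLPIEHTVMSRYWIHPLFGSKLNYWPQMKYPTYEWVRNRGYNH
CIWQMMYYRVECMFIESI
>marker03 synthetic single-copy marker
SYMRCWMKFMKIWGELQFKNWTEPGMAGTPNRCLSFIEIGNQFRFTKTFQSTMMNTEVAY
VQAVNWCIYGVAELRAIGMICGILSAQKFIIWYEKQMDKVFPTCKWWPTLQGLCFWADDG
EATKGTIGLYLRGMKYCSKVIDGYKPQMIPVATGTVRFPCEGGKTSCAESIYRAMYNH
>marker04 synthetic single-copy marker
GQKRAYGCWGMTSCERKHLDNQIINLNTKMWTKHMTAAIHSMFCDQSCVQYWHAHRFYAY
QCQHQGLAYHDDMGTISDSNSHMGYMYPWHRWASCDMIIEYLIACNDFEAIWSGTLHVGT
FAHCGKLCWARTEPAIGCPVNWCLLSWQADGGVKTR
>marker05 synthetic single-copy marker
SQDSSIWAFYCYLFFIYVQMDFEEDICPYDTMLLSNSWLMDQLCRVSTYEDVSWYCTFHI
MGEADDYDDWVDHHAGPMFKNAHWMVMTIKRVNQPRQQIERCLPYICFDPDSVHRPMSDI
CHKNATARAQYGGDQWQHLSKEMRRKIE
>marker06 synthetic single-copy marker
TRDGGPKCFNQWIANLAVTPCAEEELHECKPIANIVWFQDRHDWYKIYHCHFRRRKNAEI
DNHANISHQFGGIWCNIRSSVNTCSQSETSRNCCMSDSPKMIFWFDTFMCLNNAQVKMRG
FMKYNKHGEGVHIMQYKQKTDAVICHCDTHLSTMRLKSALAGHTVQMYM
>marker07 synthetic single-copy marker
TNYLRCCRFHHDCAILDSPCYLLYSWWYLDNEHMEDIHRSMDGGVTPFHMNMYKICRQHR
EEEMQVPSYKAKHFLAIDYKGHGYDISIAMNRQRPFEWVRYDCEPEDPEEQFTMSHELPG
QTIKYPNTWCKQIMTQFNSMSQAGMQYRPSPFTDEYYQSTDRQPHSYAESKSYTSMY
>marker08 synthetic single-copy marker
QVKHWLDRANITNIWPFVAYEFVVVTMDIEMITQLLYTPICDCGQQMEAVCVTNLARDNF
HMWFTLQEHAVSSPSGWIAWNQGWLTAYCHDWYTYYKNEMIDQEHHKNQFGDTITREHLF
AVVVPLKTPFNEHCFFAECELGVSKFDTVLVWEVANSRG
>marker09 synthetic single-copy marker
ITQLCYYCCDQGRNICVYQPVTGQSFAYNVRIPPGMGLNMPVAWECLQLWYPAIWWICLL
PLFPWTMHPFYIEYAITLIWFYMPEAPTMPMRQGKTVCANKGEIENNCQAIENVWYVREG
TGDANWKQYTMNHEPFK
>marker10 synthetic single-copy marker
RAAVLLISPPHPPNAKKEIPDTYRWCHQNQIAMWEVKCRNEHWWPISQRYAVFDIIWYRF
CTWERYDFLRKSTKWLRPLCTLEATRTFAFASSVIDGKTAMAYYCVQIIGACSAVNMTHF
SMVCILNALLLPNKDQGCLFQNGNGDDDRQWDNGHPTVWHVCRMSLCGYIA
>marker11 synthetic single-copy marker
FPIREQWIVRKTACQQVVKRKKATVMVRRYEWIWIHYDFQVFHWERYGYRVYCSPQIKPM
ETWATDPKTSQFTQLVQVDYGRVWSWFPNDDYHMNCIIDQWYSIDHMLMKYDDHSRIHAT
EDPEATCWEWQVGTLYWDPPMGKILNTEQCYSMGRMWWFFCLLCEALEHHIQPCECSMIP
WRDRYHCDERQ
>marker12 synthetic single-copy marker
IKRTFPDEGEPYMIHRAAICGSWEERSTVSNFRQQYYWTRCCEYSVAMRPADAIRLFIQG
VLIYEYDAMNQFCFIRSFTPSPWQREFWGRGPCRCIDREAWGAEHMFFCGCNWQKPYNWI
PPFNEKPGHCSSNHTLIYNLLLSMVEYIVFLYPLGWQGYRRCGDWVNVEQAWKKGNMRRI
RDRVKM
>marker13 synthetic single-copy marker
PWFHYDAWGLQIWGGWCQRVDADMFELDWHGTLPEEHWMILGGSRSGKCNWCVQVQPSRA
PAKVYCPHFFREHIACYHPQFYDPLQHQYHDVKQFKCAQKGYFYIHNNLFDDGPMTTTPE
EHEFENIWKEIAMQ
>marker14 synthetic single-copy marker
RYWGRRPQIMVRHIRRDHCLCQFCIWVLFEYWFMNRRMWAAFQQFHETVQSMDRVNMVWG
APRMVYTRWYCNEKFIVCCSDPSVCMCGNEQNHWKIKRSVGSAGCGAFWPSYRIYQAPYT
FVCGDFICGTSMRFRLTGDERYRFYKAMGQHPRQMDRNMFKKRGRQMFCCSQFHNM
>marker15 synthetic single-copy marker
ICCKPDRGDFTNQGIWDQLRKMGGPSLDMHMRCEQGDATIPQHFPMQGCWPAIYWEISRH
RWRLRRQDSVDDECVICNQPLYLKGQNVRPARGFHFWNCKNRMFSFWDQNTQGRHKLYGD
QKLAINSVKGTCMATTFEECRSDNINGHAYMASSGKYGKIY
>marker16 synthetic single-copy marker
QYFTRCDVCCFQSWGILSVRLTWEKYIWPEGRLIQSTTQFFQFIHKRCIQWNTLFPGCKN
NAYTTVFNAYQKDMFLLTMHRWSVAPNWGASWISYFFAWPECCSHMCQRRIEWWIRRACM
GHWPQCQMALQTWNFRHVYRCTCEHHATANGPPAFRSVGMSYTPRHLGIPDEETRVGVPH
CESWEMYAAE
>marker17 synthetic single-copy marker
FAIFVIDDNDMEKMYAYWKGNKFMMKWKFDNRILHFNVTAVHNNRCHVQCIHGRLNYHPL
AQHPPHDCWPATTEDDWIRCVEHVVQMWAETRCWNLSKNRNHVRDVRCTKYTMHPVPERV
LNNVYEDCSCTIRKQSMRCYHDHIESSEMNPISEQECFMNWTLCCGYMYV
>marker18 synthetic single-copy marker
KDDIWCERIHPISYSSAMVKENTAMNPTIHRWTWWPDIKYCEAHRKDHAAACVRDTAYDY
PYNPESYHVSKCRKMPTWWVYIRHWIGMRNRGPTQKDKRRHYDSITIMNLFECRGWGYVR
DCAYEFSYYPDPNAPQHMHGN
>marker19 synthetic single-copy marker
CSTHIKRIRASGNSRQSNDLMYTVSRDQVSCAASAGPINITKPKAYWMKHIQIIHASHIY
SSDMESALGHGQWWDDDRDELEVRYGTCCEPPPKTNEMGGQDKTSRPHNSCFINIWWIES
GRHIGNTGSICKACEYVYYDVMETKDQSIMPTYYIRIQFHDGPPERWRSPQNGHMRSHVN
FLQASLHVLN
>marker20 synthetic single-copy marker
HHVRAVLAAPTNAMDPRMMMGVKPKVMWATYMYQLLCNSYSSIDCAGMHCGQLYQHYLPP
QIDLFYKGDLVHVGVKNMKPMGCWALRTYMRASGHCIMAGLYQEEHVFTRVNNMVGLPMG
MSTISISVNSYSCCPFFERDRDHSNWPQLQIWGWYLHEETNASFNRSLAGGKTSMRVSWV
NYNECSHGGF
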