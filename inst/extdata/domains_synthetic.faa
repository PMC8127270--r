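>Ale_GAG|GAG|Copia|Ale
HKLIVARETLRFASDKMERSKATVASIQPLWVAGPQLELAGTSVSSFPQTFRYWPNENDVHPELMSSTWDALHVKLLELIVVVLLDGPGNYPAWLEARHH
>Ale_PR|PR|Copia|Ale
VWNIMCHKPGVMLSVRDRDADVAGALAAANGDKLQINRHVGQGGARPINAVGKIVLKFTS
>Ale_INT|INT|Copia|Ale
LNPRVLEDAKAPKALEGSFVEHSTQEVPNKHLCQNKACLKSDTEPIRFANTEAKSASYVIEAWGLLVNTTQSFCGGQHGSGVCILIFIHFLPTAFASESPLRYPIQTKTRPENTNRAYTLDGGIDSVAALLALNDVIKTQ
>Ale_RT|RT|Copia|Ale
AAIAYLAMIRNFISNPMVLKLSMQLMTLEFHQTIANKPSGDFTTFLFVFPRHVLEPSVERKDFSGVMLKAPLIVLLSRWVTNDGTTLPGQGKRDVFVHKAIVSELETTEREVAPREDRAMQLRPGLFASLTSQIFKKRGQEVAARSTLNKNGSPIERISY
>Ale_RH|RH|Copia|Ale
LERAKGGFVIALRLRKGETATARVRISKEVVIKNTVRYGVLEFFKGLAFVSPTKEFFAVMQPSSEVRCLHDHRISKYISKNLDHRINKYH
>Angela_GAG|GAG|Copia|Angela
LATKGNDVPDKGNQVYEPFEHLMPRLFKLSMTTHSRNHSLGVVLQTQGGLILPYKFVNLASKEDDISTSPSEESRQSEFKEADDEGSKSQLHVVVTTGKI
>Angela_PR|PR|Copia|Angela
GTKMKNARISYGPQRIINLAYYRDPHGDGFIKKQIPHSADYIFSAVIFRRKSWSLSKKPM
>Angela_INT|INT|Copia|Angela
NEDFVAVAKFNLVKVNKGSLMFFVITGTGLLTIISTKELGELSGLYFWVLGFLPPPPIQVTHRLVRTDPKQKYANVKKDLKREEVVTPKKTVADTTYVMGFKFEGVDMLLLDSNVFGVMSSGAIGQIGDALVNLLGSPNK
>Angela_RT|RT|Copia|Angela
EDLSYCFDTVIDVFAIGRRGTGIAFLAAEDLLPGAGLTDTNKSNKRGCQILKFEEELLDPLIVEAVRSNYQKGRRSELYKLEVTQWFKKKSVKTIYLLLDDDRFAAYEYSNLRNEGTVRIRFKPTEREAEPCANGAVANPPTGFLKLVVYIHTHDYRCLL
>Angela_RH|RH|Copia|Angela
LGLGCSRPDGKIMVPFDLKSVAFKARVPLGDKLQMIYRSKTESVCDSKTLAARKLNDGGGKPTLQVDDTAVARSAVVYDMLHDVTTDIKG
>Tekay_GAG|GAG|Gypsy|Tekay
FSSPFETDSFRDEPVSPKAGQEEIQAGKKHVKCVRGNVVFTGLPSGSYDGDKTWSQRTSILIFKNLVIFLSCQVRAQAQGKHLVMMGDHSYSILGVLGTG
>Tekay_PR|PR|Gypsy|Tekay
RRKLESLTILACLVYGLLLFRGNLKLWYRPDAYGGGEPARRVYIPSKEARMHRREAVVVL
>Tekay_INT|INT|Gypsy|Tekay
CWSFFDSVWGEDFPLFYSGREGIVQRREKWGFIQLILGHPLDNAQLPVTQALNLYGNGTLSRLVNDIIESKYPCLPQGALLLPDDDPYEFLNMMNPGARGFKSKRNVLTIMAAQAFASNAVADMDLSIQVSFQGYVADKA
>Tekay_RT|RT|Gypsy|Tekay
ENAEVEDALYVLGFGAKFVVQCSGKYGKKQEGSQTMLDVTGANKGKKMSLIKSLFNASSAISHLHFSEGVPELLALVPKRRMPREQSLAAFDGAEVPELARLKDAAFIRLQKKMLDQLQHEKLRIAAEEELLAQSAGRKKSARIRRFFCIQASAVNIMCS
>Tekay_RH|RH|Gypsy|Tekay
IEMNLAVVIDPSGGSHDLCLQRNNQAGGCLVAGHHKKDGQDTTTCISQSLDHIEKSMRLLGLTTAVGGVGLNNENGMKEVDMPSDPKDDA
>CRM_GAG|GAG|Gypsy|CRM
LAIGDPWFMVVSKFFVFSFNGTHVGILDPCIFAIKYSHRQDRTELALEDYMLLEFATSYVSLYVDVLNVYRLNKTGVRRVVSPRSFDTLNLNADESDWII
>CRM_PR|PR|Gypsy|CRM
QIMAISKKESEYNGPDQLDGNVVLKIAVMVEMKPRQQKEIQMRSWCVTVVNREVVPRYCV
>CRM_INT|INT|Gypsy|CRM
TMLAEYRLYDRAALLTDFVKGAGGASTQSNDQKMDEMPAQKVYIAYNHSYGGEPVVDCVKIYLAEEAGGETPPENGHGLLRPPGFTTANMTFPLCKKENKGSYEFGSHEEALDDGALGVMMESGWHGEALRNLEVDITLI
>CRM_RT|RT|Gypsy|CRM
LWIAGLVRNHGKDGMRAEKRAFHMKFSEGAGEYGFKVGKLIDDTPSTKVDPMVNFLKNEARGGYEAVPIEYLSRAVDLTRGWNTSNLPLIISFVAAVVYFVKELFEKAMFGFGVLPDSDILPRYGPCGVLLVKERQRTSLRWQQSLTPPLIERDMRLEPI
>CRM_RH|RH|Gypsy|CRM
EDAQKGLEPANGPPPESADGADKLKDYASTSNNPTDWESFEANFPGKLSLKHIGGEKTQIDEEFGALEPTAADLVNKMEPMIVEPPNGDS
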