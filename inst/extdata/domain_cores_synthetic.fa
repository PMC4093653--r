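>rt_core_ty1_copia|Ty1-copia synthetic 180-aa domain core (not a real protein)
LPQNDFQHRHWNPQWRYNKSIIRELYWCFCGQWDCVCPYTLCECCTWCRHLYFCEHHTAA
INKVYDKVTRQALSHKSNAPRKYIGYYTAGVKHCPGENRLQNNDRLTYNNNSFHVYNSCI
GCQHNWSNKGGNHGPGFLAQCSPRRWIRDLETITWGANLIPVHLATCHQKKPSRNQWFPY
>rt_core_ty3_gypsy|Ty3-gypsy synthetic 180-aa domain core (not a real protein)
GVFVWASKFHIFQEARVCNNHGQGDQDFCVDQWGWRSVCGPDINIGTGCFKCCDEWETEC
ERLSDTLQTVGFIGPIWPLERRYIFKEQTFEDIARVTIKYDNRKKQRVSDHHLHVHKAKI
HKWAFIDRWQINFYKNKFYSTPGPKYDAEAHFVAGAVRRIHTQFCPNCSNQHWPWHRHEG
>rt_core_line|LINE synthetic 180-aa domain core (not a real protein)
SYELEPDFNQNAYPFQPLYRHVCALRQCPEAVYDEKSYWKLFTQTTLKQPVFSQTPCNPG
DQDAAPEWRGTIKPYTLSRDGCHDNHVFGRIVWEVKCQCQFQYLGCTGVNPVIFCEETWK
FWIHANFKAIYCDEINQVPANHDPASSWITHDLIFSFQHHQSFFLCAYDIACFIHKPLIA
>tpase_core_cacta|CACTA synthetic 180-aa domain core (not a real protein)
RETFTTDKKYNLDRKYTHQIWVPAWQRRLYPVTRKKIEVDLEPHPESWTAVPVVCIEWID
NNQETYPYENVKDHCLQNWLNPVTDATRYFWSVPEHKAIYEVFRWTYCCATLVDDEFSPQ
ITPHYRCWPENHICCLHVPITDTRYYSRNNTQCQTPRNRTCYLWYNHCWRVTVFFKHAVQ
>tpase_core_hat|hAT synthetic 180-aa domain core (not a real protein)
TPFLDFVFWEIECLAKEVIFKPSAAAYSKAEQNEVQFHKVALHQGVFYLRPVCEFQRSFL
ARYDHWCWPNDLKVYEYRELHGNADLCGLSWWHCNCQHPSNWQEDKQDPAWVYPKTKVAC
FNDSYWHCWLEPRYYSKSDDDRKRENCRHCCGNHWIFDCVFRSGCCPCLWCQFASWAKVN
>tpase_core_mule|MULE synthetic 180-aa domain core (not a real protein)
DVQQYWSAEDLWVVAWPRYDIYSDSVCHERHFKHLGSFNVGKQCYIVQRADCGCIRKGGN
AAFAWELLKYYSFPCPIEPEAVGCCITCTFGGSFWDFHVAQPTAAGGQTGCIHLARLWWR
HNNTNNKNDPGWGKPVETSARVTRYAWCIIKCEHNRVDYKWDLNGPRSYGQEPWENESGF
>tpase_core_pif_harbinger|PIF/Harbinger synthetic 180-aa domain core (not a real protein)
GPFGDKWWRFHSWNTENWWRHQLVRFLAWCKTSPVTLGCVWLRFPWPKNFGFPDCEWKKK
VEIHVCSSLWPAKTEYNKLCGTRQSWGQTQRLNNWRLNKHCCYGRDNQWEQPCDSNNNTL
KIWAAILDLSKSVQWALQQFAWDTCRYFGSDLFSDWEVGSWLITNVFPDIEPTAKEFFAH
>rep_helicase_core_helitron|Helitron synthetic 180-aa domain core (not a real protein)
PYSDILYKCDLVDCWKSYHAGLENYWHWANRTLLFKAHTACCNGFPNHWVFDIKIKYRSN
FTNYFPAWDQPHRDSQQNNKGTGFPQANHKAYYLPEKTTYIIQRHLLAQEKATDNHTKSA
RYTVFDNRFSQHFFCYNAIDLHTPIKRFKFPWAPSFLCVEVWKWSDDFALPKDRPHNGVG
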