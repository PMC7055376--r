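>SMC synthetic seed protein
EEDGNVFVPGHEMKEEWIIQGCPVVEQNRVIPLAAGADTRSARTKISSCGLQDKKTSYVR
PEGKRIMNSPIGGAFGKSHDETTVIMGVSFVGKEQGKYAHKLDAKHEIWVTEKVEFDANR
EKVGNADENDRIDARGFEGAVSLMRDTSVMCIISWEEFVADHQAAVEVIFTLQKSRKAMV
VWYTSWTMLRGLDDPQLAGAKETSPLQLGSAGGSMDLESLGYKSYDKAVAGSKSNENLAF
FFYAGVNIEVIHKGIKYAEKVDKALLPMEMTFYGLLYVTELMELPAAAKSNIVDGALNIY
KDLKHVGPNLVVKRHKFSNQAEITLCPLRFPLVVGLEVLLDAAEVMDKVTERDSLQLVAI
KSKLEGKHGVPSMNVKSLRLATVFPTLETMSRQYNETQIKGIVKELKYKAETGGTTDNYY
EITLVHLGIHSQHVKDKQKLSKELPNTILFGLSMSVPLRAPGLVYERAGNAGNKYILGQI
GISEIVIIRVGLTTNIARDGLSLDANVGYVGKFMDRAKTANIIEPTEDVVIMYQPNFRIE
ELAIRMGKISRIDKQSVLFKKPGGYEAFEFEKIHPQPVERYEVRKDWELSFDSQSLTDYS
ESGAHVSECPPVTDEVAGIVYRERYVTQKGDEGMDGGSTIINGGTWARVDEPALKAHIQA
YRRLELIRKNALVDAAEISRESGTVSVVYDEPSVDILRTLIIHGAEIELLIRFKNDENIA
EFPSGPQAIRIQISYYVSQYFLQTDIAEGISFDEDPLHEASPLSVNLVTRNELWKEGKLC
IEGSGVLTQGDRQFEDLLHVTVRFIRGIDNYLAVEMLSVQAPVLYEPDIDAKISRFETYI
LRILFFEEPLGELDLFLFELLLIWKTILRGAAEMLTWQAAFQELNGIRTNLYVSIQVRHI
GALPWQNTARTETFLSDHVSLGNMHGTITNPSRGVTAITGVKIGKDAFPEKPRLLKSDLG
PIKASELLDAEQSAYTEGYATQKYLWLTVQYGQVLLRMKRAADKTKLCIKMIAEGRVLYI
VHLMWILVAYFARYDSEHEDALVIFMPILKVLEVIISRRDNVLIQGYLQKTRPVMKGEEE
QIRATEAEGGQSEQGDFGKDFGLLLRDHDKQHQALNVHNSRVCFEVLALRKKRQPVAILE
AAGVLQDVRMSIIEASNAVILLGAAFVSRGLAVVKIGNKQ
>SCPA synthetic seed protein
LLDVKFIILLKFIKSFALGIIQAGYAYRVITGINNYEVQLVGRRIPMDLVQQKGKNVTEV
KSIDLVKNSGICIQLDFAQINGDLYGKEGGVGGIDSNEELAALVYVELLKHSGQYVSDYL
QETASSYFKGLALVRVDSELEAEKSSCFERSKRLYYFAKRYLTLASNQALAVKVKYMDSV
SASGSDGVLDPPDAQITNTTQYVPDLSGADATINTLLSAI
>SCPB synthetic seed protein
LRRYIEVLRFPILRSWHEIPMATLFSGIKRDMEVVAQEDMRLFAHAIFARTGIAFALING
AGGRDMDAQFLMSRKRAPEIEEGPEQGDKGDGKGRGNKYLLEFPEGVNLKHYPAEGVKMI
TEFSKSKTFLRRFFLETTVEDRDAAEHRLEVKGPFREVADLVTQAHKGNDRDDSIVKERM
KAYDNITKSI
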