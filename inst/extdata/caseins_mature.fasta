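>beta-casein offset=1 variant=A2 mature chain (signal peptide removed)
RELEELNVPGEIVESLSSSEESITRINKKIEKFQSEEQQQTEDELQDKIH
PFAQTQSLVYPFPGPIPNSLPQNIPPLTQTPVVVPPFLQPEVMGVSKVKE
AMAPKHKEMPFPKYPVEPFTESQSLTLTDVENLHLPLPLLQSWMHQPHQP
LPPTVMFPPQSVLSLSQSKVLPVPQKAVPYPQRDMPIQAFLLYQEPVLGP
VRGPFPIIV
>alphaS1-casein offset=1 variant=B mature chain (signal peptide removed)
RPKHPIKHQGLPQEVLNENLLRFFVAPFPEVFGKEKVNELSKDIGSESTE
DQAMEDIKQMEAESISSSEEIVPNSVEQKHIQKEDVPSERYLGYLEQLLR
LKKYKVPQLEIVPNSAEERLHSMKEGIHAQQKEPMIGVNQELAYFYPELF
RQFYQLDAYPSGAWYYVPLGTQYTDAPSFSDIPNPIGSENSEKTTMPLW
>alphaS2-casein offset=1 variant=A mature chain (signal peptide removed)
KNTMEHVSSSEESIISQETYKQEKNMAINPSKENLCSTFCKEVVRNANEE
EYSIGSSSEESAEVATEEVKITVDDKHYQKALNEINQFYQKFPQYLQYLY
QGPIVLNPWDQVKRNAVPITPTLNREQLSTSEENSKKTVDMESTEVFTKK
TKLTEEEKNRLNFLKKISQRYQKFALPQYLKTVYQHQKAMKPWIQPKTKV
IPYVRYL
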