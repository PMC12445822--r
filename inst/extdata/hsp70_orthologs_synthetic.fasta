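>Hs
SRHEITEFLQCFFDKEQRRSLNWQFLLLAVIEAVGMVMYNQWVGVGTWQGPKDQRKFWAPAVVEEECWHKRLIGERKFGD
PNDRLQRFWPQSANSQPKFEEVWMMAAGRKTWNPNPRRLTVQVFNVKINGISPLSCHMVYPSFTNDMQLTGRSKKRKDMR
MRVWIHLPKWWHYDNPDPGKSQDFAFSKPFGWVPRYLLWDSLMYECMAIFCLAQLKTWGKEVKLGRWGYVLDHLTFCCKK
>Dr
SRHEITEFLQCFFDKEQRRSLNWQFLLLAVIEAVGMVMYNQWVGVGTWQGPKDQRKFWAPAVVEEECWHKRLIGERKFGD
PNDRLQRFWPQSNNSQPKFDEVWMMAAGRKTWNPNPRRLTVQVGNYKINGGRPLSCHMVYPSFTNDMQLWGRSKKRKDYR
MRVWIHLPKWWHYDNPDWGKSQDFALSKPFGWVPRYLLWDSLAYECMAIFCKAQLKTWPKEVKLGRWGYVLDHLTFCCQK
>Tb
SRHEITEDLQCFFDKTQRRSLNWQFLFLAVTEAVGMVMYNQWAGVRVWQGPKDQRKFWAPANVEEEEWHKRLIGERKFGD
PNDRLQRFWPQSANSQPKFELVWMMAAMRSTWQPNPRRLTVQVFNYKINGISRHSCGMVYNSQTWDMQLTKRLNARKDMR
MEVWIHLPKWRHYDLIDPGKSGDFATSKPFGWVPRYLLWDSLMDETMCIFCKAQLMTWGKEVKLGRWGYVLDHLTFVCKK
>Sc
EVHEITEFIFCFFDKEQRLQLRWQFLWLAVITAVGMVMFNQFVGVLTNQGRKDQRKFWAPAEVEEECCHKRLIGERKFGD
PNDRLCRFWKQSAYSQPAFGPVWMMAHCRMTWNPNPMRLTVQVLNLGINGISPLSCHMEYPSVTNDMQLTGRSAWRKCMR
MRNWIHLPKWWHYDNPDPGKSQDFASSKPFGWVPRYLLWFSLMYFCMAIFWKAQLKTWGKEDWLGRWGAVLDHQTFCCMK
>Dm
SRHEILEILQCFFDKEQRSCMRWRFLLLAPIEAFGMVMYNQWVGVGTWQPPKDQEKFWAPLVVEHECWHKRLIGERKFGD
PNDRLQRFWIQSANSVPKFEEVWMMAADPKTMNPNPRRLTVQVFNVKINGISKLSCHMVYPSFTNDMQVTGRSKKRKDMR
MRVWIHLPKWWHYDQPRPGKSQDFAFMKPFGWVLCGLLWDSLRYECHAIFCLAQLKTWYKEVKLGRWGYVLDHLTFFCRK
>Ec
SRHLCTEFFQCTADKRQRLNLNWQFLLLKVIEIVGMVMYLQWVGVGTWDGPPDNRWIWATAFVEEEIWHKRLIGERRFGD
PNDRLKRFWPQSAVSQPKFTEVIMMAAGQKTWCENPRYLTVQVRHVKIGGISPLWCHEVYPLFTNDMALTGRSKKMKDMY
MRVSKHLPKWWHYDNPDPGKYPDFAFSKKFGWCPRYLHIDSLMYPCMAIFCLAQLKTNGKEVKLGIWGYVLDHLTFCCRK
>Pa
SRHFITEFCQCFFIKEQRQSLNWIFLLQAFWEAVEMVMYNQWKGSGTWQGPKDQRKFWAPAVHEEECWEKRLIGERRFGD
PTDMLQRFWPQSANSNPAWTEVGMMAAGRKTWNPNPDRLTVQVGNVKINGISPLSCHMVYPSETNDNQLTGRVKKRKDMR
WRVWIHLPKWWHYDPGVIGKSQDFAFSKPFFWVPRYFQWHSLMYRCMAIFGLAQLKNWGKWVKHGTWGYVLDHLTFDYKK
>At
SRAEIKEQLQCFFDKEQRHSDNWEFLLLAMIEAVGMVMYNQWVGVGTWQGKKDQRKIWAWAVVEEECWHKRLIGERRFGD
PQHRLQRFWPHCANSQPKFEEVWMMAAGRKTMNINPRRYQVQVFNVKIRGISPLLCHMVYVSFTNWCYLTGRSKKRKDMR
GRVWIHLKKWKHQDQPLPGKSCDFAFSKPYGWVPRGALWDSLMYECMAIFCLAICEAWSKEVKLGRWGHELDGLTFYCKL
>Os
SRHEITEFLQPFFKMEQRRHLNWQCLLLALIERVFRVMANQWVGVGTWQGPKDQRKFWAPWVVEEECWHKRLIGERRFGD
PNDRLCRFWKQWAYSQPKFEEVWMMDAGRKTWNPAPRILTVQVFNEKILGISPLSCHMVYPPFTNLMQHTGRAKKRIDMR
MRVWIHEPKWWFYDNPDPGKSQDEAFSKACGWVPIYLLWDPLMYCHMAVFCLAQLKTWGKEVKLGRWGFVLDHLTFCCKK
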