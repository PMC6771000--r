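>catA_syn route=catechol_12_dioxygenation synthetic catechol 1,2-dioxygenase analog
QRWYKEYQPETHFSENTQIFVWKTISDSGGHNHHDARVEHNTFSSGLHADNQVHSQVCNRCYCQWKMNKN
HDLIWLTDHYPKMDTNPKELGLAFQWQVIRVMFAMSLYVTIQHMRWHADDRDIFGHIWCHACDCLGRRPQ
WEFFWEKIPNDEMWNAVWMEANETEYDGQEGLKTYCWTRRTVSFAWTNWTELGTPDFHYDQGTRYVKGCY
RRTTRIYPAQCSTYKDLLIAHAANDMGYSTLWVKSARWTMQCEAPRMLRCLAELCYANRWYDTTCTTVRD
IHNPSPMSPY
>catB_syn route=catechol_12_dioxygenation synthetic muconate cycloisomerase analog
AAKKLGIVSRIQVMRAFMLLCAGITQRWVLNWIPANNCRFVAGDKPAWAEWVVPKWTLVKDYRSWYREMK
VHRPLSSYPNLKASQLQHHDWDKDVQHIDVSREPILGYRSQQVHTVNTDEHPPAKSCWQQSQLEGTMQWM
DRYSYEVSQWFRGYVDWRIEMECGQWIYVTEYAAQEDGDQQYHHYVGKFTHRWGPMNEQQYRGLHECKSY
HGWTDTLQGIMAWPWGEFPVIPGEVMMCRIGAQKGASKSMSCQISWKSLW
>catC_syn route=catechol_12_dioxygenation synthetic muconolactone isomerase analog
VWNNYTDDGNDNHWLNDAEENLRSWNFSDKGWLFTIHEHWPLLIGWKCPITKFCRTYKACTCQPIPMQKV
GAECGPAATHIEYGQWVACNILESKIRVWMSIVIITNWDIRHGYNSGLYLSLVNTNDEMWLWSCNIDDVA
DQVMFQEVYEGVDFRDCWTMKVLVDIMYVHTITCVHEHHIAAHHFINNHLMCLGDKVVFQHCTNAKHVKQ
>xylE_syn route=catechol_23_dioxygenation synthetic catechol 2,3-dioxygenase analog
LYLRIRWYHDEIYVRTTFNGYGKSNIREPIIQMGFLAKNDSVAYIMMWDYAVHADDMKEDQAKQTYKCWC
NGCCIDWNHQQLGRDLWWGVYQCDYNYPIIEWSPQFNIMEVMSYKHSGEDYCWCIDRIDEGAKVDEHAGR
CAMELTQRNHYQKRLCHHAPAQMICATGFHEDEFIITHHAPDDKNYMGHHLIFMQSYYVHHYSRYGSMLR
PCVQHTHAFYLYQLQTCHIQNWIMHKLPHPKHIEKDKMNSLFTCCRPLIARRNSIKKIFVQPRLQVIPYC
RACNAWGMACTGLFNQECKE
>xylF_syn route=catechol_23_dioxygenation synthetic HMS hydrolase analog
MAPLLRRKQSTMVIRINPEINMSPSCWSHAPTGVMIIRSAKSCSDMKDPSWGAYEARASYALDMPRFSPL
MWKEGCYMMSSTFAWQVDRNSQQQFCEAMMREMNYHQTMGFNDYEGVMKTVSEARWMLDYIMMTFKNYEI
SNLIQAPNLCEPDNQAHVVLQFDRDRTYFQPTGKPWSWNTEPRVQDLSRTQKQWKEMPFGVTNAWNVRMI
EFPNHKVTKLIPVTHARDLEKAFKQKCAANLTMTIIMTRCTDLRYFDQYHPQAYMYLVLF
>xylG_syn route=catechol_23_dioxygenation synthetic HMS dehydrogenase analog
LDCGMFTYTYYSEANKNRHHDVCNYINPWMIWFELFNWEPRHYSMRMYFQCFYWTQDRFSCFQSMNYPPG
SRADHCLPNSRHNIALWAIRHLNMLDHYNKVVDVCVIKTPMAMHWKPTYVKVLAIWMDPHACWTHHINEK
KPTCLHYLQWSPQLLTDHPRGCTHCSKMKYEMREVPTHMWISGVSYANHGDIFHMGILLSDCSLCKCIYG
LEWRRDWANYDMVSWTGEKKGKAMEMAGDKFFICTCEVSI
>nahE_syn route=naphthalene_salicylate synthetic HBP hydratase-aldolase analog
EWWSWSRGGHLVQTHVTLTRFYLERWRNFVFLWTEVIGHMLYMENCDTHYGDYGQGWYFADIRRWYRNHK
ANDQAFPVYCETRQWREAGVTRPIHHKSTPSVEFGMCMKPALEYFSRQDVGCHTFDQERLSCSFQNETYT
YWQAPNLQPGNCFILWQRSQFQNFPHSKDSSGAKIYPVANYCQQHYHCYRCEVPGFPLNRTMRGNCTRGS
PQLFTPMLWHGFLAECCRFDRTSWRSWAGWAVLVGPKYGLMEAWQVIIEDKSHSVHHDRMQAICVEIWSP
CNWYKTNYQEPNYFVAAMRDKHWWWAVQMC
>nahF_syn route=naphthalene_salicylate synthetic salicylaldehyde dehydrogenase analog
QDAVVVGRVHRNKRMAFNESDVDDEAMEYQMGSTELGVGDEFYYSKVTLCFNNSPHEHGMHGKQCIPIQH
LSKTWTYIIFWTLMTWGHFFKYEFPCQTINHERYYHMYAQETDQCNGDVEDHIVTFRWMHFYKVFTTKNE
YLTRVHYWPEHTEEAETYIMTFNDARISNMLAINCDQRKYLCQNHGVCHHWCDYLCFQQYKVLVFKLFIR
TGFPEKYKICHNIYWLQRYPAAWLWMEAPGMHMWKAGTLVYCPYETSNRRSFVRKQIQWFFLENMCEPAY
>bphC_syn route=biphenyl_benzoate synthetic biphenyl-2,3-diol 1,2-dioxygenase analog
YPRAETINNRTHQPFLYCDHKVGTYEQIWEFDICHTSHEQFTEGKEKPCPRSTCKVWQHPWNRFTCYDPA
EYDAIGRCTSGRGWKSTALTAMHWIQMPTAEQVQGASNNKFSIRLIEPHYGRQYYYTQIIYCHNKIWQYE
CFDFIFFTPEYTVHWSTSWWPCQFVMYQNWRSSLGCQLNLTFKCRQCLFDGQYPTKFNNGAYFFAMLQCV
YASACYFRWVCFRHMFEIDWRTKFQWWLMIPPLNYVDALSAIHLNTVSLEMPSDDSTFHSCRHTRDTDNS
MEPPLLYMMCYHEPY
>bphD_syn route=biphenyl_benzoate synthetic 2,6-dioxo-6-phenylhexa-3-enoate hydrolase analog
KSTMCTKITWLVPTYMLYLYSSIHFEWEIMVVLSAPGDRQLDPMSYVPDKHAQAQASCYYFYVKVGGDFK
YVNMAHDCPICLHILNLVRDIKDMLGFPPRWTNSHRHLSIEPKVFQYHQRACRFWRNLGKRDEQTMMELW
WLEHLLCGSPHRMCLHTWATRKYEIRTMDKIHWKNGWCKMGGICMYRNAHHMMFHKVAYIYEDCLMEHML
VWPCEKVYVPNMPIFMELPSIDSRCMERGSDEKGHPKFQEYRTYMTRSVLAYTYD
>gtdA_syn route=gentisate synthetic gentisate 1,2-dioxygenase analog
ETLFLVIYCKVEDKNNWFNIRFIWDSRHKYLIHVRLNDRHHHEQAWCMDAHVEQMWGIMWPPMCDPEVHR
KVTGMPQERFMFINYWVGVMPLIKMVDPWHFYMFNPTTGHAASVNYQMHKINVMDYDGYRPREKYDNQSA
QSRTVQCFQRKMAITVCWSQEQIDWCTRTIQYYYFSYDPCQQMTWMRQMICQRYTHKCFTPPFYSGYSQC
FDMNPSQGIRIWAVKWKSWMQIAEAVAENRFHGWRCCRNGAISCHLPQFSISFYFYVYGIIIFELNRMKS
YNPRNSDGKWQCGNRIWFMYITKRARTYTKGTIIDVKYKQAFISTSDPRPHPCWREYPNH
>cyp_syn route=gentisate synthetic cytochrome P450 analog
PFHQKASICQNCQMVAEVKMTEGYFPLMSQYPVNSFLSEMLFISYAWHMRTNLREPVYPHDFEWITPGKN
SIWCVVCKCCFVHFDKSHNLFSPVGEVEERTHAYIAWKKVWVQFVKSKTWSWNDETCPVVRRHASCHYIK
WVIMQMCDKNGVGGDAFQYFNWSEVPPMWFTWMNCAPSSLESHQDHFICDTCDNSWFKTYKGYYCSYYHE
MHWIRHYLKWLDRRTVTPEEGLMHNTFWALCWMRDLKQHGMTNEKWGGEFAKNILEPMTCQEYKDPMLIR
AKYHFMIMAQEVSQFENRQYWDQELNVAPNWPSFGWSGCKSEEGNQTHTQSKLFATNNIPCFINYEFQEF
LKSNWTFWFNWCQWWVEFINTSGRKQMFSMCFSQDVLWPYVWGTEHMYFE
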