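"drug_code","drug_name","had_group","had_type"
"NOREPINEPHRINE","Norepinephrine","general","ANS"
"DOPAMINE","Dopamine","general","ANS"
"DOBUTAMINE","Dobutamine","general","ANS"
"CALCIUM_GLUCONATE","Calcium gluconate","general","END"
"DIGOXIN","Digoxin","general","CVS"
"ISOPROTERENOL","Isoproterenol","general","ANS"
"WARFARIN","Warfarin","general","BIG"
"MAGNESIUM_SULFATE","Magnesium sulfate","general","CVS"
"HEPARIN","Heparin","general","BIG"
"POTASSIUM_CHLORIDE","Potassium chloride","general","CVS"
"REGULAR_INSULIN","Regular insulin","general","END"
"ADRENALINE","Adrenaline","general","ANS"
"KETAMINE","Ketamine","narcotic_psychotropic","CNS"
"MIDAZOLAM","Midazolam","narcotic_psychotropic","CNS"
"PETHIDINE","Pethidine","narcotic_psychotropic","CNS"
"ALPRAZOLAM","Alprazolam","narcotic_psychotropic","CNS"
"PHENTERMINE","Phentermine","narcotic_psychotropic","ANS"
"OXYCODONE","Oxycodone","narcotic_psychotropic","CNS"
"EPHEDRINE","Ephedrine","narcotic_psychotropic","ANS"
"NITRAZEPAM","Nitrazepam","narcotic_psychotropic","CNS"
"FENTANYL","Fentanyl","narcotic_psychotropic","CNS"
"METHYLPHENIDATE_HCL","Methylphenidate HCL","narcotic_psychotropic","ANS"
"METHADONE","Methadone","narcotic_psychotropic","CNS"
"PSEUDOEPHEDRINE","Pseudoephedrine","narcotic_psychotropic","ANS"
"ZOLPIDEM","Zolpidem","narcotic_psychotropic","CNS"
"MORPHINE","Morphine","narcotic_psychotropic","CNS"
"5_FLUOROURACIL","5-Fluorouracil","iv_cytotoxic","Tumor"
"ARSENIC_TRIOXIDE","Arsenic trioxide","iv_cytotoxic","Tumor"
"AZACITIDINE","Azacitidine","iv_cytotoxic","Tumor"
"BENDAMUSTINE","Bendamustine","iv_cytotoxic","Tumor"
"BLEOMYCIN","Bleomycin","iv_cytotoxic","Tumor"
"BUSULFAN","Busulfan","iv_cytotoxic","Tumor"
"CABAZITAXEL","Cabazitaxel","iv_cytotoxic","Tumor"
"CARBOPLATIN","Carboplatin","iv_cytotoxic","Tumor"
"CARMUSTINE","Carmustine","iv_cytotoxic","Tumor"
"CISPLATIN","Cisplatin","iv_cytotoxic","Tumor"
"CLOFARABINE","Clofarabine","iv_cytotoxic","Tumor"
"CYCLOPHOSPHAMIDE","Cyclophosphamide","iv_cytotoxic","Tumor"
"CYTARABINE","Cytarabine","iv_cytotoxic","Tumor"
"DACARBAZINE","Dacarbazine","iv_cytotoxic","Tumor"
"DACTINOMYCIN","Dactinomycin","iv_cytotoxic","Tumor"
"DECITABINE","Decitabine","iv_cytotoxic","Tumor"
"DOCETAXEL","Docetaxel","iv_cytotoxic","Tumor"
"DOXORUBICIN","Doxorubicin","iv_cytotoxic","Tumor"
"EPIRUBICIN","Epirubicin","iv_cytotoxic","Tumor"
"ERIBULIN_MESYLATE","Eribulin mesylate","iv_cytotoxic","Tumor"
"ETOPOSIDE","Etoposide","iv_cytotoxic","Tumor"
"FLUDARABINE","Fludarabine","iv_cytotoxic","Tumor"
"GEMCITABINE","Gemcitabine","iv_cytotoxic","Tumor"
"IDARUBICIN","Idarubicin","iv_cytotoxic","Tumor"
"IFOSFAMIDE","Ifosfamide","iv_cytotoxic","Tumor"
"IRINOTECAN","Irinotecan","iv_cytotoxic","Tumor"
"IXABEPILONE","Ixabepilone","iv_cytotoxic","Tumor"
"L_ASPARAGINASE","L-Asparaginase","iv_cytotoxic","Tumor"
"LIPOSOMAL_DOXORUBICIN","Liposomal-doxorubicin","iv_cytotoxic","Tumor"
"MELPHALAN","Melphalan","iv_cytotoxic","Tumor"
"METHOTREXATE","Methotrexate","iv_cytotoxic","Tumor"
"MITOMYCIN_C","Mitomycin C","iv_cytotoxic","Tumor"
"MITOXANTRONE","Mitoxantrone","iv_cytotoxic","Tumor"
"OXALIPLATIN","Oxaliplatin","iv_cytotoxic","Tumor"
"PACLITAXEL","Paclitaxel","iv_cytotoxic","Tumor"
"PEMETREXED","Pemetrexed","iv_cytotoxic","Tumor"
"TOPOTECAN","Topotecan","iv_cytotoxic","Tumor"
"VINBLASTINE","Vinblastine","iv_cytotoxic","Tumor"
"VINCRISTINE_SULFATE","Vincristine sulfate","iv_cytotoxic","Tumor"
"VINORELBINE","Vinorelbine","iv_cytotoxic","Tumor"
"TEMOZOLOMIDE","Temozolomide","oral_cytotoxic","Tumor"
"TEGAFUR_URACIL","Tegafur-Uracil","oral_cytotoxic","Tumor"
"TEGAFUR_GIMERACIL_OTERACIL","Tegafur-Gimeracil-Oteracil","oral_cytotoxic","Tumor"
"CAPECITABINE","Capecitabine","oral_cytotoxic","Tumor"
"HYDROXYUREA","Hydroxyurea","oral_cytotoxic","Tumor"
"FLUDARABINE_PHOSPHATE","Fludarabine phosphate","oral_cytotoxic","Tumor"
"MERCAPTOPURINE","Mercaptopurine","oral_cytotoxic","Tumor"
"THIOGUANINE","Thioguanine","oral_cytotoxic","Tumor"
"CHLORAMBUCIL","Chlorambucil","oral_cytotoxic","Tumor"
"MAFORAN","Maforan","general","BIG"
"EMTHEXATE","Emthexate","oral_cytotoxic","Tumor"
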