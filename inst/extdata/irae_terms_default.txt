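# Default irAE preferred-term list -- SYNTHETIC PLACEHOLDER.
# This is an illustrative subset of MedDRA-style preferred terms commonly
# coded as immune-related adverse events under checkpoint inhibition. It is
# NOT the curated 106-term list used in published pharmacovigilance analyses
# (that list is distributed as supplementary material of its source and is
# a required, versioned input for any real analysis). One term per line;
# '#' starts a comment; matching is case-insensitive.
Colitis
Autoimmune colitis
Diarrhoea immune-mediated
Pneumonitis
Immune-mediated pneumonitis
Hepatitis
Autoimmune hepatitis
Hypophysitis
Hypopituitarism
Thyroiditis
Autoimmune thyroiditis
Hypothyroidism
Hyperthyroidism
Adrenal insufficiency
Type 1 diabetes mellitus
Nephritis
Autoimmune nephritis
Tubulointerstitial nephritis
Myocarditis
Autoimmune myocarditis
Myositis
Polymyositis
Rhabdomyolysis
Arthritis
Polyarthritis
Vitiligo
Rash maculo-papular
Pruritus
Dermatitis bullous
Pemphigoid
Stevens-Johnson syndrome
Uveitis
Iridocyclitis
Guillain-Barre syndrome
Myasthenia gravis
Encephalitis
Autoimmune encephalitis
Neuropathy peripheral immune-mediated
Pancreatitis
Autoimmune pancreatitis
Immune thrombocytopenia
Autoimmune haemolytic anaemia
Sarcoidosis
Vasculitis
Sjogren's syndrome
Systemic lupus erythematosus
Polymyalgia rheumatica
Hypereosinophilia
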