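# Functional categories for integrated domains (IDs) found fused into NLR
# immune receptors. Lookup order: accession, then case-insensitive name
# keyword (regular expressions, first match wins). Categories:
#   kinase | DNA-binding | other-signaling | unknown
accessions:
  PF00069: kinase           # Protein kinase domain
  PF07714: kinase           # Protein tyrosine kinase
  PF00847: DNA-binding      # AP2 domain
  PF02362: DNA-binding      # B3 DNA-binding domain
  PF02892: DNA-binding      # BED zinc finger
  PF00249: DNA-binding      # Myb-like DNA-binding domain
  PF03106: DNA-binding      # WRKY DNA-binding domain
  PF00125: DNA-binding      # Core histone H2A/H2B/H3/H4
  PF00096: DNA-binding      # C2H2 zinc finger
  PF04434: DNA-binding      # SWIM zinc finger
  PF00098: DNA-binding      # Zinc knuckle
  PF04770: DNA-binding      # ZF-HD protein dimerisation region
  PF03514: DNA-binding      # GRAS transcription regulator
  PF01419: other-signaling  # Jacalin-like lectin domain
  PF00085: other-signaling  # Thioredoxin
  PF00179: other-signaling  # Ubiquitin-conjugating enzyme
  PF01344: other-signaling  # Kelch motif
  PF03081: other-signaling  # Exo70 exocyst complex subunit
  PF00036: other-signaling  # EF-hand (calmodulin-like)
  PF00481: other-signaling  # Protein phosphatase 2C
  PF00227: other-signaling  # Proteasome subunit
  PF00161: other-signaling  # Ribosome-inactivating protein
  PF00635: other-signaling  # Major sperm protein (MSP) domain
keywords:
  "tyrosine[ -]kinase": kinase
  "kinase": kinase
  "WRKY": DNA-binding
  "AP2": DNA-binding
  "\\bB3\\b": DNA-binding
  "Myb": DNA-binding
  "zf[ -]?BED|BED[ -]?(zinc|ZnF|finger)": DNA-binding
  "zinc[ -]?(finger|knuckle)": DNA-binding
  "histone": DNA-binding
  "GRAS": DNA-binding
  "homeobox|ZF-HD": DNA-binding
  "jacalin": other-signaling
  "thioredoxin": other-signaling
  "ubiquitin[ -]conjugat": other-signaling
  "kelch": other-signaling
  "Exo70": other-signaling
  "calmodulin": other-signaling
  "phosphatase": other-signaling
  "proteasome": other-signaling
  "lectin": other-signaling
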