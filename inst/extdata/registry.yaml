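# Antimicrobial ingredient registry for national veterinary import surveillance.
# Importance categories encode the WOAH (veterinary) and WHO (human medicine)
# list editions current for the 2017-2021 Fiji study window.
#   woah: VCIA | VHIA | VIA | UNCLASSIFIED
#   who:  CIA_HIGHEST | CIA_HIGH | HIGHLY_IMPORTANT | IMPORTANT | UNCLASSIFIED
# iu_to_mg: mg of active ingredient per international unit, present for
# ingredients imported in IU-denominated formulations (penicillin G:
# 1 mg ~ 1667 IU, i.e. 0.0006 mg/IU).
list_edition:
  woah: "OIE list of antimicrobials of veterinary importance (2021)"
  who: "WHO critically important antimicrobials for human medicine, 6th rev."
synonyms:
  gentamycin sulphate: gentamycin
  gentamicin: gentamycin
  gentamicin sulphate: gentamycin
  cephalothin sodium: cephalothin
  cephazolin sodium: cephazolin
  cefazolin: cephazolin
  cefuroxime sodium: cefuroxime
  ciprofloxacin hydrochloride: ciprofloxacin
  lincomycin hydrochloride monohydrate: lincomycin
  lincomycin hydrochloride: lincomycin
  penicillin g procaine: penicillin
  penicillin g: penicillin
  benzylpenicillin: penicillin
  procaine penicillin: penicillin
  silver sulfadiazine: sulfadiazine
  tetracycline hydrochloride: tetracycline
  oxytetracycline hydrochloride: oxytetracycline
ingredients:
  - name: gentamycin
    class: Aminoglycosides
    woah: VCIA
    who: CIA_HIGH
  - name: cephalothin
    class: Cephalosporins
    subclass: First-generation cephalosporin
    woah: VHIA
    who: HIGHLY_IMPORTANT
  - name: cephazolin
    class: Cephalosporins
    subclass: First-generation cephalosporin
    woah: VHIA
    who: HIGHLY_IMPORTANT
  - name: cefuroxime
    class: Cephalosporins
    subclass: Second-generation cephalosporin
    woah: VHIA
    who: HIGHLY_IMPORTANT
  - name: ciprofloxacin
    class: Quinolones
    subclass: Fluoroquinolone
    woah: VCIA
    who: CIA_HIGHEST
  - name: norfloxacin
    class: Quinolones
    subclass: Fluoroquinolone
    woah: VCIA
    who: CIA_HIGHEST
  - name: lincomycin
    class: Lincosamides
    woah: VHIA
    who: HIGHLY_IMPORTANT
  - name: erythromycin
    class: Macrolides
    woah: VCIA
    who: CIA_HIGHEST
  - name: penicillin
    class: Penicillins
    woah: VCIA
    who: CIA_HIGH
    iu_to_mg: 0.0006
  - name: sulfadiazine
    class: Sulfonamides
    woah: VCIA
    who: HIGHLY_IMPORTANT
  - name: sulfamethoxazole
    class: Sulfonamides
    woah: VCIA
    who: HIGHLY_IMPORTANT
  - name: tetracycline
    class: Tetracyclines
    woah: VCIA
    who: HIGHLY_IMPORTANT
  - name: oxytetracycline
    class: Tetracyclines
    woah: VCIA
    who: HIGHLY_IMPORTANT
  - name: metronidazole
    class: Nitroimidazoles
    woah: UNCLASSIFIED
    who: UNCLASSIFIED
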