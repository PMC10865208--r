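# Default extraction lexicon: referral-reason (ReRe) and patient-goal (PaG)
# categories with Dutch code-word patterns, section markers and unification
# rewrites. Patterns are regular expressions matched case-insensitively on
# normalized (lower-cased, ASCII-transliterated) text with substring
# semantics, so "pijn" also fires inside compounds such as "pijnklachten".
# The code-word lists are a reconstruction built from the published category
# exemplars plus documented extensions; site-specific deployments are
# expected to edit this file.
referral_reason:
  SecondOpinionReRe:
    - "aanvullend onderzoek"
    - "aanvullende diagnostiek"
    - "nadere diagnostiek"
    - "second opinion"
    - "2e mening"
  AnesthesiologyReRe:
    - "blokkade"
    - "pijnbestrijding"
    - "anesthesiolog"
    - "injectie"
    - "pijnpoli"
  RehabReRe:
    - "revalidatie"
    - "reactivering"
    - "multidisciplinair"
  AdviceReRe:
    - "advies"
    - "advisering"
  OptionsReRe:
    - "behandelbare opties"
    - "behandelopties"
    - "behandelmogelijkheden"
patient_goal:
  MoreCausePaG:
    - "2e mening"
    - "oorzaak"
    - "diagnose"
    - "wat er aan de hand is"
  PainRedPaG:
    - "pijn"
  BetterFuncPaG:
    - "functioneren"
    - "belastbaarheid"
    - "behandelopties"
  AdvicePaG:
    - "advies"
section_markers:
  referral_reason:
    - "reden van verwijzing"
    - "reden verwijzing"
    - "verwijsreden"
    - "verwijzing voor"
  patient_goal:
    - "hulpvraag"
    - "vraag van patient"
    - "wens van patient"
    - "doel van patient"
unification_rules:
  - pattern: "tweede mening"
    replacement: "2e mening"
  - pattern: "2de mening"
    replacement: "2e mening"
  - pattern: "blockade|blocade"
    replacement: "blokkade"
fallback_whole_letter: true
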