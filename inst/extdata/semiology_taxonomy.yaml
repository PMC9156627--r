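# Default semiology taxonomy: the twelve most common ictal categories plus
# the postictal and asymptomatic categories. Patterns are case-insensitive
# regular expressions anchored on word boundaries; `exclude` lists longer
# terms that must not trigger the category; `negation_window` is the number
# of tokens before a match within which a negation cue suppresses it.
version: "0.1"
categories:
  Tonic:
    kind: ictal
    include:
      - "\\btonic\\b"
      - "stiff(ening)? postur"
    exclude:
      - "tonic[- ]clonic"
      - "clonic[- ]tonic"
    negation_window: 3
  Oral and manual automatisms:
    kind: ictal
    include:
      - "lip[- ]?smacking"
      - "\\bchewing\\b"
      - "oro[- ]?alimentary"
      - "orofacial automatism"
      - "manual automatism"
      - "upper limb automatism"
      - "\\bautomotor\\b"
      - "\\bfiddling\\b"
      - "pedal automatism"
      - "ictal drinking"
      - "ictal swallowing"
    negation_window: 3
  Dialeptic-LOA-LOC:
    kind: ictal
    include:
      - "blank stare"
      - "loss of (awareness|contact|consciousness)"
      - "\\bunaware\\b"
      - "psychomotor arrest"
      - "distant gaze"
      - "dreamy state"
      - "dyscognitive"
      - "\\bdialeptic\\b"
    negation_window: 3
  Epigastric:
    kind: ictal
    include:
      - "epigastric"
      - "abdominal (rising|aura|sensation)"
      - "butterfl(y|ies) sensation"
    negation_window: 3
  Vocalization - unintelligible noises:
    kind: ictal
    include:
      - "vocali[sz]ation"
      - "\\bgrunting\\b"
      - "\\bmumbling\\b"
      - "\\bhumming\\b"
    exclude:
      - "ictal speech"
    negation_window: 3
  Autonomic:
    kind: ictal
    include:
      - "autonomic"
      - "pilomotor|piloerection"
      - "urinary urge"
      - "hypopn(o)?ea"
      - "laryngeal constriction"
      - "hypersalivation"
      - "ictal (tachycardia|bradycardia)"
      - "\\bflushing\\b"
    negation_window: 3
  Olfactory:
    kind: ictal
    include:
      - "olfactory"
      - "ictal smell"
      - "smell of"
      - "\\bodou?r\\b"
    negation_window: 3
  Head version:
    kind: ictal
    include:
      - "head version"
      - "versive head"
      - "forced head (deviation|turn)"
      - "extreme head turn"
    exclude:
      - "unforced head turn"
    negation_window: 3
  Dystonic:
    kind: ictal
    include:
      - "dystoni(a|c)"
      - "twisted posture"
    negation_window: 3
  Other automatisms:
    kind: ictal
    include:
      - "\\bgelastic\\b"
      - "\\bdacrystic\\b"
      - "ictal cough"
      - "\\bblinking\\b"
      - "nose[- ]?wiping"
      - "face[- ]?rubbing"
      - "ictal laugh(ter|ing)?"
      - "ictal cry(ing)?"
    negation_window: 3
  Mimetic automatisms:
    kind: ictal
    include:
      - "grimac(e|ing)"
      - "\\bmimetic\\b"
      - "raising of (the )?eyebrows"
      - "(fearful|downturned mouth) (facial )?expression"
      - "facial expression"
      - "chapeau de gendarme"
    negation_window: 3
  Somatosensory:
    kind: ictal
    include:
      - "somatosensory"
      - "\\btingling\\b"
      - "par(a)?esthesia"
      - "\\bnumbness\\b"
      - "touch sensation"
    negation_window: 3
  Postictal:
    kind: postictal
    include:
      - "post[- ]?ictal"
    negation_window: 3
  Asymptomatic:
    kind: asymptomatic
    include:
      - "asymptomatic"
      - "no (reported )?(symptoms|semiology)"
      - "silent stimulation"
    negation_window: 0
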