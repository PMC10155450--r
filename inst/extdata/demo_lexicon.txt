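# Demonstration symptom lexicon: lay surface forms -> canonical symptoms.
# Matching is on normalized tokens (lowercase, apostrophes removed), so
# "can't sleep" is written here as "cant sleep".

canonical: auditory hallucination
  variant: auditory hallucination
  variant: auditory hallucinations
  variant: hearing voices
  variant: hear voices
  variant: heard voices

canonical: visual hallucination
  variant: visual hallucination
  variant: visual hallucinations
  variant: seeing things
  variant: visions

canonical: schizophrenia
  variant: schizophrenia
  variant: schizophrenic

canonical: fear
  variant: fear
  variant: fears
  variant: afraid
  variant: scared

canonical: delusion
  variant: delusion
  variant: delusions
  variant: delusional

canonical: psychosis
  variant: psychosis
  variant: psychotic

canonical: paranoia
  variant: paranoia
  variant: paranoid

canonical: suicide
  variant: suicide
  variant: suicidal

canonical: pain
  variant: pain
  variant: painful
  variant: aching

canonical: trauma
  variant: trauma
  variant: traumatic
  variant: traumatised
  variant: traumatized

canonical: depression
  variant: depression
  variant: depressed

canonical: anxiety
  variant: anxiety
  variant: anxious

canonical: loneliness
  variant: loneliness
  variant: lonely

canonical: low mood
  variant: low mood

canonical: lethargy
  variant: lethargy
  variant: lethargic

canonical: lack of sleep
  variant: lack of sleep
  variant: cant sleep
  variant: couldnt sleep
  variant: sleepless
  variant: insomnia
  variant: sleep

canonical: panic attacks
  variant: panic attacks
  variant: panic attack
  variant: panic

canonical: dissociation
  variant: dissociation
  variant: dissociative
  variant: dissociating

canonical: obsession
  variant: obsession
  variant: obsessions
  variant: obsessive

canonical: compulsion
  variant: compulsion
  variant: compulsions
  variant: compulsive

canonical: hypertension
  variant: hypertension
  variant: high blood pressure

canonical: nausea
  variant: nausea
  variant: nauseous

canonical: weight loss
  variant: weight loss
  variant: losing weight

canonical: head
  variant: head
  variant: headache
  variant: headaches

canonical: apprehension
  variant: apprehension
  variant: apprehensions

canonical: sadness
  variant: sad
  variant: sadness

canonical: anger
  variant: anger
  variant: angry

canonical: guilt
  variant: guilt
  variant: guilty

[blacklist]
medication
medications
doctor
doctors
hospital
therapist
school
money
family
friends
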