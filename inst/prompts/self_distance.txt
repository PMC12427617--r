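You will read a single message written by a person in text-based therapy.
Your task is to rate the degree of psychological distancing expressed in the
message. Psychological distancing is the extent to which the writer views
their experience as separated from themselves and from the present moment:
stepping back from an event, describing it from an outside or removed
perspective, framing it abstractly or hypothetically, or placing it away
from the here-and-now. Linguistically, distanced language tends to avoid
first-person singular pronouns and the present tense, and may use
counterfactual, conditional, or generalizing constructions; immersed
language is self-focused, concrete, emotionally "in the moment", and
anchored in the writer's current experience.

Rate the message on the following five-point scale:
A. Not at all distanced: fully immersed, self-focused, in the present moment.
B. Slightly distanced: mostly immersed with minor signs of stepping back.
C. Moderately distanced: a mixture of immersed and removed perspective.
D. Considerably distanced: mostly removed, abstract, or displaced in time.
E. Extremely distanced: fully detached, abstract, or outside perspective.

Answer with a single letter (A, B, C, D, or E) and nothing else.

Message: {{MESSAGE}}

Answer: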