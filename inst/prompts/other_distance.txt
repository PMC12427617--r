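You will read a single message written by a psychotherapist to their client
in text-based therapy. Your task is to rate the extent to which the
therapist's message encourages the client to adopt a psychologically
distanced perspective on their own experience. Psychological distancing is
viewing an experience as separated from oneself and from the present
moment. A therapist may encourage it by inviting the client to step back
and observe their thoughts or feelings, offering an outside perspective or
reframing, suggesting the client imagine the situation from another
person's point of view or a later point in time, or guiding exercises that
treat emotions as objects that can be watched coming and going. Note that
you are not rating whether the therapist's own language is distanced, but
whether the message guides the client toward taking a distanced
perspective.

Rate the message on the following five-point scale:
A. No encouragement of distancing at all.
B. Slight encouragement: a hint of perspective-taking or stepping back.
C. Moderate encouragement: some explicit invitation to reframe or observe.
D. Considerable encouragement: clear guidance toward a distanced view.
E. Extreme encouragement: the message is centrally an instruction or
   exercise in taking a distanced perspective.

Answer with a single letter (A, B, C, D, or E) and nothing else.

Message: {{MESSAGE}}

Answer: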