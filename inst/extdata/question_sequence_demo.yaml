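# Two-step relevance/sentiment question sequence: Q1 routes irrelevant
# posts straight to END; relevant posts get the sentiment question, whose
# answers are tagged with the class they vote for.
start: Q1
questions:
  - id: Q1
    text: "Is this post relevant to vaccinations?"
    answers:
      - id: a1_1
        text: "Yes, it is relevant"
        next: Q2
      - id: a1_2
        text: "No, it is irrelevant"
        label: irrelevant
        next: END
  - id: Q2
    text: "What attitude toward vaccinations does this post express?"
    answers:
      - id: a2_1
        text: "Positive / supportive"
        label: positive
        next: END
      - id: a2_2
        text: "Negative / opposed"
        label: negative
        next: END
      - id: a2_3
        text: "Neutral / other"
        label: neutral
        next: END
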