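# Minimal declarative model in the epimem schema: a two-place world with a
# noisy light sensor. Rows of each table block are next-state (B) or outcome
# (A) rows; B lists one block per action.
horizon: 3
factors:
  - name: place
    states: [here, there]
    actions: [stay, go]
    B:
      - - [1.0, 0.0]
        - [0.0, 1.0]
      - - [0.0, 1.0]
        - [1.0, 0.0]
  - name: light
    states: [on, off]
    B:
      - [0.9, 0.1]
      - [0.1, 0.9]
modalities:
  - name: eye
    outcomes: [bright, dark]
    parents: [light]
    A:
      - [0.8, 0.2]
      - [0.2, 0.8]
D:
  place: [1.0, 0.0]
  light: [0.5, 0.5]
policies:
  actions:
    - [go, stay]
    - [stay, stay]
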