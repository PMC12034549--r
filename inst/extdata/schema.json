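{
  "attributes": [
    {
      "name": "Age",
      "codes": [1, 2, 3, 4, 5],
      "meanings": {
        "1": "25-30",
        "2": "30-35",
        "3": "35-40",
        "4": "40-45",
        "5": "45-50"
      }
    },
    {
      "name": "Feeling sad or Tearful",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "sometimes",
        "3": "no"
      }
    },
    {
      "name": "Irritable towards baby and partner",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "sometimes",
        "3": "no"
      }
    },
    {
      "name": "Trouble sleeping at night",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "two or more days a week",
        "3": "no"
      }
    },
    {
      "name": "Problems concentrating or making decision",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "often",
        "3": "no"
      }
    },
    {
      "name": "Overeating or loss of appetite",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "not at all",
        "3": "no"
      }
    },
    {
      "name": "Suicide attempt",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "not interested to say",
        "3": "no"
      }
    },
    {
      "name": "Feeling of guilt",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "maybe",
        "3": "no"
      }
    },
    {
      "name": "Problems of bonding with baby",
      "codes": [1, 2, 3],
      "meanings": {
        "1": "yes",
        "2": "sometimes",
        "3": "no"
      }
    },
    {
      "name": "Feeling anxious",
      "codes": [1, 2],
      "meanings": {
        "1": "yes",
        "2": "no"
      }
    }
  ],
  "target_name": "Feeling anxious",
  "positive_code": 1
}
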