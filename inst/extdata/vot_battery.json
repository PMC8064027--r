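[
  {
    "test_id": "rvf_deficit",
    "domain": "low_level",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "visual_acuity",
    "domain": "low_level",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "lpost",
    "domain": "low_level",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "delayed_match_words",
    "domain": "word",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "surprise_recog_words",
    "domain": "word",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "lexical_decision",
    "domain": "word",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      },
      {
        "measure_id": "rt",
        "direction": "lower_is_better"
      }
    ]
  },
  {
    "test_id": "word_reading",
    "domain": "word",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      },
      {
        "measure_id": "rt",
        "direction": "lower_is_better"
      }
    ]
  },
  {
    "test_id": "regular_word_reading",
    "domain": "word",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "exception_word_reading",
    "domain": "word",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "nonword_reading",
    "domain": "word",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "text_reading",
    "domain": "word",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "delayed_match_objects",
    "domain": "object",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "surprise_recog_objects",
    "domain": "object",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "object_decision",
    "domain": "object",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      },
      {
        "measure_id": "rt",
        "direction": "lower_is_better"
      }
    ]
  },
  {
    "test_id": "picture_naming",
    "domain": "object",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      },
      {
        "measure_id": "rt",
        "direction": "lower_is_better"
      }
    ]
  },
  {
    "test_id": "chmt",
    "domain": "object",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "object_categorisation",
    "domain": "object",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "delayed_match_faces",
    "domain": "face",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "surprise_recog_faces",
    "domain": "face",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "face_familiarity",
    "domain": "face",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      },
      {
        "measure_id": "rt",
        "direction": "lower_is_better"
      }
    ]
  },
  {
    "test_id": "famous_face_naming",
    "domain": "face",
    "in_composite": true,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  },
  {
    "test_id": "cfmt",
    "domain": "face",
    "in_composite": false,
    "measures": [
      {
        "measure_id": "accuracy",
        "direction": "higher_is_better"
      }
    ]
  }
]
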