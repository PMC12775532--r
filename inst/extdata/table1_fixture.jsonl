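{"participant_id":"TBL1","group":"NC","picture_id":1,"word_count":23,"tokens":[{"surface":"Yakışıklı","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"yakışıklı","agreement_subject":false}},{"surface":"bir","is_punct":false,"is_stopword":false,"pos":"det","features":{"determiner":"none","case":"none","plural":false,"lemma":"bir","agreement_subject":false}},{"surface":"adam","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"indefinite","case":"none","plural":false,"lemma":"adam","agreement_subject":false}},{"surface":"Bu","is_punct":false,"is_stopword":false,"pos":"det","features":{"determiner":"none","case":"none","plural":false,"lemma":"bu","agreement_subject":false}},{"surface":"adam","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"demonstrative","case":"none","plural":false,"lemma":"adam","agreement_subject":false}},{"surface":"çalışan","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"çalışan","agreement_subject":false}},{"surface":"olmalı","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"olmalı","agreement_subject":false}},{"surface":"Adam","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":false,"lemma":"adam","agreement_subject":false}},{"surface":"tarlada","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"tarlada","agreement_subject":false}},{"surface":"çalışıyor","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"çalışıyor","agreement_subject":false}},{"surface":"Adam","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":false,"lemma":"adam","agreement_subject":false}},{"surface":"tarlayı","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"accusative","plural":false,"lemma":"tarla","agreement_subject":false}},{"surface":"sürüyor","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"sürüyor","agreement_subject":false}},{"surface":"Evler","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":true,"lemma":"ev","agreement_subject":false}},{"surface":"var","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"var","agreement_subject":false}},{"surface":"Köy","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":false,"lemma":"köy","agreement_subject":false}},{"surface":"hayatını","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":false,"lemma":"hayat","agreement_subject":false}},{"surface":"anlatıyor","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"anlatıyor","agreement_subject":false}},{"surface":"Kız","is_punct":false,"is_stopword":false,"pos":"noun","features":{"determiner":"none","case":"none","plural":false,"lemma":"kız","agreement_subject":false}},{"surface":"var","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"var","agreement_subject":false}},{"surface":"Genç","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"genç","agreement_subject":false}},{"surface":"ve","is_punct":false,"is_stopword":false,"pos":"other","features":{"determiner":"none","case":"none","plural":false,"lemma":"ve","agreement_subject":false}},{"surface":"güzel","is_punct":false,"is_stopword":false,"pos":"verb","features":{"determiner":"none","case":"none","plural":false,"lemma":"güzel","agreement_subject":true}}]}
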