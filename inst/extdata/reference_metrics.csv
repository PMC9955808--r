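classifier,mas_level,precision,recall,support
gaussian_nb,0,0.50,0.43,7
gaussian_nb,1,0.86,0.67,9
gaussian_nb,1+,1.00,0.29,7
gaussian_nb,2,0.25,1.00,2
gaussian_nb,3,0.50,1.00,2
decision_tree,0,0.63,0.71,7
decision_tree,1,0.63,0.56,9
decision_tree,1+,0.80,0.57,7
decision_tree,2,0.50,1.00,2
decision_tree,3,1.00,1.00,2
random_forest,0,0.75,0.86,7
random_forest,1,1.00,0.67,9
random_forest,1+,0.86,0.86,7
random_forest,2,0.67,1.00,2
random_forest,3,0.67,1.00,2
xgboost,0,0.67,0.57,7
xgboost,1,0.88,0.78,9
xgboost,1+,1.00,0.71,7
xgboost,2,0.67,1.00,2
xgboost,3,0.40,1.00,2
logical_svm_rf,0,0.86,0.86,7
logical_svm_rf,1,1.00,0.89,9
logical_svm_rf,1+,1.00,0.86,7
logical_svm_rf,2,0.67,1.00,2
logical_svm_rf,3,0.67,1.00,2
logical_svm_rf,4,1.00,1.00,1
svm,0,0.67,0.86,7
svm,1,1.00,0.78,9
svm,1+,0.83,0.71,7
svm,2,0.33,0.50,2
svm,3,1.00,1.00,2
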